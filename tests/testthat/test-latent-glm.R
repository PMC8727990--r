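test_that("marginal log-likelihood matches a hand-summed mixture", {
  # 3 individuals, all nine mixture terms written out explicitly
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3), c(0.25, 0.5, 0.25))
  post <- genotype_posterior_from_probs(probs)
  y <- c(0.4, -1.1, 2.0)
  z <- c(1, -1, 0.5)
  theta <- list(alpha = 0.2, beta = 0.5, gamma = -0.3, sigma2 = 1.4)

  expected <- 0
  for (i in 1:3) {
    s <- 0
    for (g in 0:2) {
      mu <- 0.2 + 0.5 * g + (-0.3) * z[i]
      dens <- exp(-(y[i] - mu)^2 / (2 * 1.4)) / sqrt(2 * pi * 1.4)
      s <- s + probs[i, g + 1] * dens
    }
    expected <- expected + log(s)
  }
  expect_equal(latent_loglik(theta, y, post, Z = cbind(z)), expected,
               tolerance = 1e-10)

  # binomial branch, same toy
  yb <- c(1, 0, 1)
  thb <- list(alpha = -0.2, beta = 0.8, gamma = 0.4)
  expected_b <- 0
  for (i in 1:3) {
    s <- 0
    for (g in 0:2) {
      p <- 1 / (1 + exp(-(-0.2 + 0.8 * g + 0.4 * z[i])))
      s <- s + probs[i, g + 1] * (if (yb[i] == 1) p else 1 - p)
    }
    expected_b <- expected_b + log(s)
  }
  expect_equal(latent_loglik(thb, yb, post, Z = cbind(z),
                             family = "binomial"), expected_b,
               tolerance = 1e-10)
})

test_that("with beta = 0 the likelihood does not depend on the posterior", {
  set.seed(31)
  y <- rnorm(20)
  theta <- list(alpha = 0.1, beta = 0, gamma = numeric(0), sigma2 = 1)
  p1 <- genotype_posterior_from_probs(matrix(runif(60), 20, 3))
  p2 <- genotype_posterior_from_probs(matrix(runif(60), 20, 3))
  expect_equal(latent_loglik(theta, y, p1), latent_loglik(theta, y, p2),
               tolerance = 1e-12)
})

test_that("certain genotypes reduce the latent fit to the classical GLM", {
  set.seed(32)
  n <- 120
  g <- rbinom(n, 2, 0.4)
  Z <- cbind(rnorm(n))
  y <- 0.4 * g + 0.7 * Z[, 1] + rnorm(n)
  post <- degenerate_posterior(g)

  fit <- fit_latent(y, post, Z)
  ols <- lm(y ~ g + Z)
  expect_equal(unname(fit$coefficients),
               unname(coef(ols)[c(1, 2, 3)]), tolerance = 1e-8)
  # SEs equal the closed form with the MLE residual variance
  X <- cbind(1, g, Z)
  s2_mle <- sum(residuals(ols)^2) / n
  expect_equal(unname(fit$se[1:3]),
               unname(sqrt(diag(solve(crossprod(X))) * s2_mle)),
               tolerance = 1e-6)
  # dosage fit on the same data is identical in beta
  fd <- fit_dosage(y, post, Z)
  expect_equal(fd$coefficients[["beta"]], fit$coefficients[["beta"]],
               tolerance = 1e-8)

  # binomial reduction against glm()
  yb <- rbinom(n, 1, plogis(0.5 * g - 0.3))
  fitb <- fit_latent(yb, post, family = "binomial")
  glmb <- glm(yb ~ g, family = binomial)
  expect_equal(unname(fitb$coefficients), unname(coef(glmb)),
               tolerance = 1e-6)
  expect_equal(fitb$se_beta, summary(glmb)$coefficients[2, 2],
               tolerance = 1e-4)
  expect_lte(fitb$iterations, 3)
})

test_that("EM estimates match direct numerical maximization", {
  set.seed(33)
  for (rep in 1:20) {
    family <- sample(c("gaussian", "binomial"), 1)
    site <- sim_site(n = 60, f = runif(1, 0.2, 0.6),
                     depth = runif(1, 1, 4), beta = runif(1, -0.8, 0.8),
                     family = family)
    fit <- fit_latent(site$y, site$post, family = family, tol = 1e-10)
    oracle <- numeric_latent_mle(site$y, site$post, family = family)
    expect_lt(abs(fit$coefficients[["beta"]] - oracle$beta), 1e-4)
    expect_monotone_trace(fit)
  }
})

test_that("EM log-likelihood is non-decreasing for every family", {
  set.seed(34)
  for (family in c("gaussian", "binomial", "poisson")) {
    site <- sim_site(n = 150, depth = 1.5, beta = 0.4, family = family,
                     with_cov = TRUE)
    fit <- fit_latent(site$y, site$post, site$Z, family = family,
                      prime = FALSE)
    expect_monotone_trace(fit)
    expect_true(fit$converged)
  }
})

test_that("dosage priming leaves the optimum unchanged and speeds the EM", {
  set.seed(35)
  n_faster <- 0
  for (rep in 1:60) {
    site <- sim_site(n = 300, f = 0.45, depth = 2, beta = 0.3)
    # tight tolerance: the claim is about the converged optimum, not the
    # truncation point of the default stopping rule
    fp <- fit_latent(site$y, site$post, prime = TRUE, tol = 1e-12,
                     max_iter = 500)
    f0 <- fit_latent(site$y, site$post, prime = FALSE, tol = 1e-12,
                     max_iter = 500)
    if (rep <= 50)
      expect_lt(abs(fp$coefficients[["beta"]] - f0$coefficients[["beta"]]),
                1e-6)
    n_faster <- n_faster + (fp$iterations <= f0$iterations)
  }
  expect_gte(n_faster / 60, 0.9)

  # with certain genotypes the primed start is already the optimum
  set.seed(36)
  g <- rbinom(80, 2, 0.4)
  y <- 0.5 * g + rnorm(80)
  fit <- fit_latent(y, degenerate_posterior(g))
  expect_lte(fit$iterations, 2)
  theta0 <- prime_from_dosage(y, degenerate_posterior(g))
  expect_equal(theta0$beta, fit$coefficients[["beta"]], tolerance = 1e-8)
})

test_that("observed-information SEs match an independent numerical Hessian", {
  skip_if_not_installed("pracma")
  set.seed(37)
  site <- sim_site(n = 10, f = 0.4, depth = 2, beta = 0.5)
  fit <- fit_latent(site$y, site$post, tol = 1e-12)
  v <- c(fit$theta$alpha, fit$theta$beta, fit$theta$sigma2)
  H <- pracma::hessian(function(p) {
    latent_loglik(list(alpha = p[1], beta = p[2], gamma = numeric(0),
                       sigma2 = p[3]), site$y, site$post)
  }, v)
  se_oracle <- sqrt(diag(solve(-H)))
  fi <- fisher_se(fit$theta, site$y, site$post)
  expect_equal(unname(fi$se), se_oracle, tolerance = 1e-4)

  # binomial family too
  set.seed(38)
  siteb <- sim_site(n = 40, depth = 2, beta = 0.6, family = "binomial")
  fitb <- fit_latent(siteb$y, siteb$post, family = "binomial", tol = 1e-12)
  vb <- c(fitb$theta$alpha, fitb$theta$beta)
  Hb <- pracma::hessian(function(p) {
    latent_loglik(list(alpha = p[1], beta = p[2], gamma = numeric(0)),
                  siteb$y, siteb$post, family = "binomial")
  }, vb)
  fib <- fisher_se(fitb$theta, siteb$y, siteb$post, family = "binomial")
  expect_equal(unname(fib$se), sqrt(diag(solve(-Hb))), tolerance = 1e-4)
})

test_that("dosage fit equals the closed-form simple regression slope", {
  set.seed(39)
  site <- sim_site(n = 100, depth = 2, beta = 0.4)
  d <- dosage(site$post)
  fd <- fit_dosage(site$y, site$post)
  expect_equal(fd$coefficients[["beta"]],
               cov(d, site$y) / var(d), tolerance = 1e-10)
  # invariant to likelihood rescaling
  gl2 <- genotype_likelihoods(exp(site$gl$loglik) * runif(100, 0.5, 2),
                              depth = site$gl$depth)
  post2 <- genotype_posterior(gl2, prior_sample_af(0.45))
  fd2 <- fit_dosage(site$y, post2)
  expect_equal(fd2$coefficients[["beta"]], fd$coefficients[["beta"]],
               tolerance = 1e-10)
})

test_that("score test reduces to the classical Rao statistic and handles
           degenerate sites", {
  set.seed(40)
  n <- 150
  g <- rbinom(n, 2, 0.35)
  Z <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  post <- degenerate_posterior(g)

  y <- 0.2 * g + 0.4 * Z[, 1] + rnorm(n)
  st <- score_test(y, post, Z)
  expect_equal(st$statistic, classical_score_stat(y, g, Z), tolerance = 1e-6)

  yb <- rbinom(n, 1, plogis(0.3 * g - 0.2 * Z[, 1]))
  stb <- score_test(yb, post, Z, family = "binomial")
  expect_equal(stb$statistic, classical_score_stat(yb, g, Z, "binomial"),
               tolerance = 1e-6)
  # agreement with the stats-package Rao test as a second, independent route
  expect_equal(stb$statistic,
               anova(glm(yb ~ Z + g, family = binomial), test = "Rao")[3, "Rao"],
               tolerance = 1e-6)

  # identical posteriors across individuals carry no genotype signal
  flat <- genotype_posterior_from_probs(matrix(rep(c(0.25, 0.5, 0.25), n),
                                               n, 3, byrow = TRUE))
  st0 <- score_test(y, flat)
  expect_equal(st0$statistic, 0)
  expect_equal(st0$pvalue, 1)
  # the latent fit flags such sites as non-estimable
  f0 <- fit_latent(y, flat)
  expect_false(f0$estimable)
  expect_true(is.na(f0$pvalue))
})

test_that("hybrid reports the score branch for null sites and the exact EM
           fit for significant ones", {
  set.seed(41)
  # null site: phenotype independent of genotype
  site0 <- sim_site(n = 300, depth = 2, beta = 0)
  y0 <- rnorm(300)
  h0 <- fit_hybrid(y0, site0$post, screen_alpha = 1e-4)
  expect_equal(h0$branch, "score")
  expect_null(h0$coefficients)

  # strong site passes the screen and reproduces fit_latent exactly
  site1 <- sim_site(n = 300, depth = 2, beta = 0.8)
  h1 <- fit_hybrid(site1$y, site1$post)
  expect_equal(h1$branch, "latent")
  f1 <- fit_latent(site1$y, site1$post)
  expect_equal(h1$coefficients, f1$coefficients)
  expect_equal(h1$pvalue, f1$pvalue)

  # sweep: wherever the screen passes, hybrid p equals latent p
  set.seed(42)
  for (rep in 1:40) {
    site <- sim_site(n = 150, depth = 1.5, beta = runif(1, 0, 0.5))
    h <- fit_hybrid(site$y, site$post)
    if (h$branch == "latent")
      expect_equal(h$pvalue, fit_latent(site$y, site$post)$pvalue)
    else
      expect_gte(h$pvalue, 0.05)
  }
})

test_that("wald and likelihood-ratio tests agree asymptotically", {
  set.seed(43)
  site <- sim_site(n = 800, depth = 3, beta = 0.25)
  fw <- fit_latent(site$y, site$post, test = "wald")
  fl <- fit_latent(site$y, site$post, test = "lrt")
  expect_equal(fw$coefficients, fl$coefficients)
  expect_lt(abs(log10(fw$pvalue) - log10(fl$pvalue)), 0.35)
})

test_that("tidy and glance summarize fits as tibbles", {
  set.seed(44)
  site <- sim_site(n = 100, depth = 3, beta = 0.5, with_cov = TRUE)
  fit <- fit_latent(site$y, site$post, site$Z)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta", "gamma1"))
  expect_equal(td$estimate[2], fit$coefficients[["beta"]])
  gl <- glance(fit)
  expect_equal(gl$p.value, fit$pvalue)
  expect_true(gl$converged)
  expect_s3_class(td, "tbl_df")
})

test_that("latent fits reject malformed designs", {
  site <- sim_site(n = 30, depth = 2, beta = 0)
  expect_error(fit_latent(site$y[-1], site$post), "match")
  expect_error(fit_latent(site$y, site$post, family = "binomial"), "0/1")
  expect_error(fit_latent(c(site$y[-1], NA), site$post), "missing")
  Zbad <- cbind(1, rep(2, 30))  # collinear with the intercept
  expect_error(fit_latent(site$y, site$post, Zbad), "singular|collinear")
})
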