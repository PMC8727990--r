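# Shared fixture builders. All data are generated in code under fixed seeds.

# posterior placing all mass on the true genotypes (certain-genotype limit)
degenerate_posterior <- function(g) {
  genotype_posterior_from_probs(diag(3)[g + 1L, , drop = FALSE])
}

# one simulated site: genotypes at `f`, reads at `depth`, posterior under
# the true-frequency HWE prior, and a phenotype with genotype effect `beta`
sim_site <- function(n, f = 0.45, depth = 4, beta = 0.3, family = "gaussian",
                     with_cov = FALSE) {
  g <- stats::rbinom(n, 2, f)
  gl <- simulate_genotype_likelihoods(g, depth)
  post <- genotype_posterior(gl, prior_sample_af(f))
  Z <- if (with_cov) cbind(stats::rnorm(n)) else NULL
  lin <- beta * g + if (with_cov) 0.5 * Z[, 1] else 0
  y <- switch(family,
    gaussian = stats::rnorm(n, lin, 1),
    binomial = stats::rbinom(n, 1, stats::plogis(lin - 0.3)),
    poisson = stats::rpois(n, exp(0.1 * lin)))
  list(g = g, gl = gl, post = post, y = y, Z = Z)
}

# classical Rao score statistic for adding `g` to a null GLM of y on (1, Z)
classical_score_stat <- function(y, g, Z = NULL, family = "gaussian") {
  X0 <- cbind(rep(1, length(y)), Z)
  if (family == "gaussian") {
    f0 <- stats::lm.fit(X0, y)
    r <- f0$residuals
    s2 <- sum(r^2) / length(y)  # null MLE dispersion
    gt <- stats::lm.fit(X0, g)$residuals
    sum(g * r)^2 / (s2 * sum(g * gt))
  } else {
    fam <- if (family == "binomial") stats::binomial() else stats::poisson()
    f0 <- suppressWarnings(stats::glm.fit(X0, y, family = fam))
    mu <- f0$fitted.values
    W <- if (family == "binomial") mu * (1 - mu) else mu
    U <- sum(g * (y - mu))
    i_eff <- sum(W * g^2) -
      drop(t(W * g) %*% X0 %*% solve(crossprod(X0, X0 * W),
                                     crossprod(X0, W * g)))
    U^2 / i_eff
  }
}

# direct numerical maximization of the marginal latent log-likelihood,
# independent of the EM path (oracle)
numeric_latent_mle <- function(y, post, Z = NULL, family = "gaussian") {
  n_gamma <- if (is.null(Z)) 0L else ncol(Z)
  gaussian <- family == "gaussian"
  obj <- function(v) {
    theta <- list(alpha = v[1], beta = v[2],
                  gamma = if (n_gamma) v[2 + seq_len(n_gamma)]
                          else numeric(0),
                  sigma2 = if (gaussian) exp(v[length(v)]))
    -latent_loglik(theta, y, post, Z, family)
  }
  start <- c(mean(y), 0, rep(0, n_gamma), if (gaussian) log(stats::var(y)))
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(alpha = opt$par[1], beta = opt$par[2], value = -opt$value)
}

expect_monotone_trace <- function(fit, tol = 1e-8) {
  expect_true(all(diff(fit$loglik_trace) > -tol))
}

# write a small BEAGLE file and companion phenotype table in a temp dir
write_toy_beagle <- function(lines, file = tempfile(fileext = ".beagle")) {
  writeLines(lines, file)
  file
}
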