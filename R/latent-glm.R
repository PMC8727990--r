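#' @importFrom stats pchisq plogis dpois var lm.wfit glm.fit
#'   binomial poisson glm.control
NULL

# ---- family machinery -------------------------------------------------------

check_family <- function(family) {
  match.arg(family, c("gaussian", "binomial", "poisson"))
}

check_response <- function(y, family) {
  if (anyNA(y)) stop("phenotype contains missing values", call. = FALSE)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 phenotype", call. = FALSE)
  if (family == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("poisson family requires non-negative integer counts", call. = FALSE)
  invisible(y)
}

# log f(y | eta) elementwise; `eta` may be an N x 3 matrix (y recycled by row)
logf_family <- function(y, eta, family, sigma2 = NULL) {
  switch(family,
    gaussian = -0.5 * base::log(2 * pi * sigma2) - (y - eta)^2 / (2 * sigma2),
    binomial = y * plogis(eta, log.p = TRUE) +
      (1 - y) * plogis(-eta, log.p = TRUE),
    poisson = y * eta - exp(eta) - lfactorial(y)
  )
}

# d log f / d eta
dlogf_deta <- function(y, eta, family, sigma2 = NULL) {
  switch(family,
    gaussian = (y - eta) / sigma2,
    binomial = y - plogis(eta),
    poisson = y - exp(eta)
  )
}

# ---- theta ------------------------------------------------------------------

theta_new <- function(alpha, beta, gamma = numeric(0), sigma2 = NULL) {
  list(alpha = alpha, beta = beta, gamma = gamma, sigma2 = sigma2)
}

flatten_theta <- function(theta) {
  v <- c(alpha = theta$alpha, beta = theta$beta)
  if (length(theta$gamma))
    v <- c(v, stats::setNames(theta$gamma,
                              paste0("gamma", seq_along(theta$gamma))))
  if (!is.null(theta$sigma2)) v <- c(v, sigma2 = theta$sigma2)
  v
}

unflatten_theta <- function(v, n_gamma, has_sigma2) {
  theta_new(v[[1]], v[[2]],
            gamma = if (n_gamma) v[2L + seq_len(n_gamma)] else numeric(0),
            sigma2 = if (has_sigma2) v[[length(v)]] else NULL)
}

# linear predictor for each candidate genotype: N x 3
eta_matrix <- function(theta, Z, n) {
  base <- rep_len(theta$alpha +
    if (length(theta$gamma)) drop(Z %*% theta$gamma) else 0, n)
  cbind(base, base + theta$beta, base + 2 * theta$beta, deparse.level = 0)
}

check_design <- function(y, post, Z, family) {
  stopifnot(inherits(post, "genotype_posterior"))
  n <- nrow(post$probs)
  if (length(y) != n)
    stop("phenotype length does not match posterior", call. = FALSE)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n)
      stop("covariate rows do not match posterior", call. = FALSE)
    if (anyNA(Z)) stop("covariates contain missing values", call. = FALSE)
  }
  check_response(y, family)
  Z
}

#' Marginal log-likelihood of the latent-genotype GLM
#'
#' The observed-data log-likelihood of the latent-genotype model,
#' \deqn{\ell(\theta) = \sum_i \log \sum_{g \in \{0,1,2\}}
#'   p(y_i \mid G_i = g, z_i, \theta)\, p(G_i = g \mid x_i),}
#' where \eqn{p(G_i = g \mid x_i)} is the genotype posterior and the mean of
#' \eqn{y_i} given \eqn{G_i = g} is the linear predictor
#' \eqn{\eta_{ig} = \alpha + \beta g + z_i^\top \gamma} through the family
#' link (identity, logit or log).
#'
#' @param theta list with `alpha`, `beta`, `gamma` (covariate effects, may
#'   be empty) and, for the gaussian family, `sigma2`.
#' @param y phenotype vector.
#' @param post a [genotype_posterior].
#' @param Z optional covariate matrix.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @return scalar log-likelihood.
#' @export
latent_loglik <- function(theta, y, post, Z = NULL, family = "gaussian") {
  family <- check_family(family)
  Z <- check_design(y, post, Z, family)
  if (family == "gaussian" && (is.null(theta$sigma2) || theta$sigma2 <= 0))
    stop("gaussian family requires sigma2 > 0", call. = FALSE)
  theta$gamma <- theta$gamma %||% numeric(0)
  n <- length(y)
  eta <- eta_matrix(theta, Z, n)
  lw <- base::log(post$probs) + logf_family(y, eta, family, theta$sigma2)
  ll <- log_row_sum_exp(lw)
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood at individual ",
         which(!is.finite(ll))[1], call. = FALSE)
  sum(ll)
}

log_row_sum_exp <- function(lw) {
  m <- pmax(lw[, 1], lw[, 2], lw[, 3])
  m + base::log(rowSums(exp(lw - m)))
}

# ---- ordinary GLM core (dosage / true-genotype / null fits) -----------------

# Minimal weighted GLM on a prebuilt design matrix. Returns conventional
# coefficients, SEs (dispersion n-p for gaussian), and the MLE sigma2 used
# by the latent machinery.
glm_basic <- function(X, y, family, weights = NULL) {
  n <- nrow(X)
  p <- ncol(X)
  w <- weights %||% rep(1, n)
  if (family == "gaussian") {
    fit <- lm.wfit(X, y, w)
    if (fit$rank < p)
      stop("singular fit: design matrix is collinear", call. = FALSE)
    rss <- sum(w * fit$residuals^2)
    wn <- sum(w)
    sigma2_mle <- rss / wn
    R <- qr.R(fit$qr)
    xtx_inv <- chol2inv(R)
    se <- sqrt(diag(xtx_inv) * rss / (wn - p))
    loglik <- -wn / 2 * (base::log(2 * pi * sigma2_mle) + 1)
    coef <- fit$coefficients
  } else {
    fam <- if (family == "binomial") binomial() else poisson()
    fit <- suppressWarnings(
      glm.fit(X, y, weights = w, family = fam,
              control = glm.control(epsilon = 1e-10, maxit = 100L)))
    if (fit$rank < p)
      stop("singular fit: design matrix is collinear", call. = FALSE)
    coef <- fit$coefficients
    Qr <- fit$qr
    covmat <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    se <- sqrt(diag(covmat))
    mu <- fit$fitted.values
    loglik <- if (family == "binomial")
      sum(w * (y * base::log(mu) + (1 - y) * base::log1p(-mu)))
    else
      sum(w * dpois(y, mu, log = TRUE))
    sigma2_mle <- NULL
  }
  list(coefficients = coef, se = se, loglik = loglik, sigma2 = sigma2_mle,
       rank = fit$rank, fitted = fit$fitted.values)
}

new_latent_fit <- function(method, family, n, theta = NULL, coefficients = NULL,
                           se = NULL, se_beta = NA_real_, loglik = NA_real_,
                           loglik_trace = numeric(0), iterations = NA_integer_,
                           converged = NA, statistic = NA_real_,
                           pvalue = NA_real_, estimable = TRUE,
                           branch = NA_character_, freq = NA_real_) {
  structure(list(method = method, family = family, n = n, theta = theta,
                 coefficients = coefficients, se = se, se_beta = se_beta,
                 loglik = loglik, loglik_trace = loglik_trace,
                 iterations = iterations, converged = converged,
                 statistic = statistic, pvalue = pvalue,
                 estimable = estimable, branch = branch, freq = freq),
            class = "latent_fit")
}

not_estimable_fit <- function(method, family, n) {
  new_latent_fit(method, family, n, estimable = FALSE)
}

wald_p <- function(beta, se) pchisq((beta / se)^2, df = 1, lower.tail = FALSE)

#' Dosage-based association fit
#'
#' Standard GLM of the phenotype on `(1, dosage, Z)`, where the dosage is
#' the posterior mean genotype. This is the conventional way of feeding
#' genotype uncertainty into an association test; it discards all posterior
#' information beyond the mean. Wald test on the dosage coefficient.
#'
#' @inheritParams latent_loglik
#' @return a `latent_fit` object (`method = "dosage"`).
#' @export
fit_dosage <- function(y, post, Z = NULL, family = "gaussian") {
  family <- check_family(family)
  Z <- check_design(y, post, Z, family)
  n <- length(y)
  if (var(post$dosage) < 1e-8)
    return(not_estimable_fit("dosage", family, n))
  X <- cbind(1, post$dosage, Z)
  fit <- glm_basic(X, y, family)
  beta <- fit$coefficients[[2]]
  se_b <- fit$se[[2]]
  n_gamma <- ncol(X) - 2L
  theta <- theta_new(fit$coefficients[[1]], beta,
                     gamma = if (n_gamma) fit$coefficients[-(1:2)]
                             else numeric(0),
                     sigma2 = fit$sigma2)
  coefs <- stats::setNames(unname(fit$coefficients),
                           c("alpha", "beta",
                             if (n_gamma) paste0("gamma", seq_len(n_gamma))))
  new_latent_fit("dosage", family, n, theta = theta,
                 coefficients = coefs, se = unname(fit$se), se_beta = se_b,
                 loglik = fit$loglik, iterations = 1L, converged = TRUE,
                 statistic = (beta / se_b)^2, pvalue = wald_p(beta, se_b))
}

#' EM starting values from a dosage regression ("priming")
#'
#' Fits the dosage GLM and returns its coefficients as starting values for
#' the latent-model EM (for the gaussian family the residual variance from
#' the dosage fit, with the maximum-likelihood N denominator, is used as
#' the starting `sigma2`). Starting the EM here rather than at zero
#' drastically reduces the number of iterations to convergence while
#' leaving the converged fit unchanged.
#'
#' @inheritParams latent_loglik
#' @return a theta list (`alpha`, `beta`, `gamma`, `sigma2`).
#' @export
prime_from_dosage <- function(y, post, Z = NULL, family = "gaussian") {
  family <- check_family(family)
  Z <- check_design(y, post, Z, family)
  X <- cbind(1, post$dosage, Z)
  fit <- glm_basic(X, y, family)
  theta_new(fit$coefficients[[1]], fit$coefficients[[2]],
            gamma = if (ncol(X) > 2) fit$coefficients[-(1:2)] else numeric(0),
            sigma2 = fit$sigma2)
}

# neutral start: intercept at the link of the phenotype mean, beta = 0
theta_null_start <- function(y, Z, family) {
  n_gamma <- if (is.null(Z)) 0L else ncol(Z)
  mu <- mean(y)
  alpha <- switch(family,
    gaussian = mu,
    binomial = stats::qlogis(min(max(mu, 1e-6), 1 - 1e-6)),
    poisson = base::log(max(mu, 1e-6)))
  theta_new(alpha, 0, gamma = rep(0, n_gamma),
            sigma2 = if (family == "gaussian") var(y) else NULL)
}

#' Latent-genotype EM association fit
#'
#' Fits the latent-genotype GLM by maximizing the marginal likelihood
#' ([latent_loglik]) with an EM algorithm in which the unobserved genotype
#' is the latent variable. The E-step computes genotype responsibilities
#' \eqn{w_{ig} \propto p(G_i = g \mid x_i)\, p(y_i \mid G_i = g, z_i,
#' \theta)}; the M-step solves a weighted GLM on the 3N-row expanded design
#' (genotype column set to g, weight \eqn{w_{ig}}) — weighted least squares
#' for the gaussian family, with \eqn{\sigma^2 \leftarrow \sum_{ig} w_{ig}
#' (y_i - \eta_{ig})^2 / N}, and weighted IRLS run to inner convergence for
#' binomial and poisson, so each M-step fully maximizes the expected
#' complete-data log-likelihood and the observed-data log-likelihood is
#' non-decreasing. Standard errors come from the observed Fisher
#' information of the marginal likelihood ([fisher_se]); the default test
#' on \eqn{\beta} is Wald against \eqn{\chi^2_1}.
#'
#' Sites where the posterior dosage variance is below 1e-8 carry no
#' information about \eqn{\beta}; they are returned flagged as
#' non-estimable with no test.
#'
#' @inheritParams latent_loglik
#' @param prime start the EM from the dosage-regression coefficients
#'   ([prime_from_dosage]) rather than from a null start.
#' @param tol convergence tolerance on the change in log-likelihood.
#' @param max_iter EM iteration cap; non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @param test `"wald"` (default) or `"lrt"` for the p-value on `beta`.
#' @param se compute standard errors (set `FALSE` to skip the information
#'   matrix, e.g. inside large simulations that only need `beta`).
#' @return a `latent_fit` object (`method = "latent"`): coefficients,
#'   `se_beta`, `loglik` and its EM trace, iteration count, convergence
#'   flag, `pvalue`.
#' @examples
#' set.seed(1)
#' g <- rbinom(50, 2, 0.3)
#' gl <- simulate_genotype_likelihoods(g, mean_depth = 4)
#' post <- genotype_posterior(gl, prior_sample_af(0.3))
#' y <- 0.5 * g + rnorm(50)
#' fit_latent(y, post)
#' @export
fit_latent <- function(y, post, Z = NULL, family = "gaussian", prime = TRUE,
                       tol = 1e-6, max_iter = 100L, test = c("wald", "lrt"),
                       se = TRUE) {
  family <- check_family(family)
  test <- match.arg(test)
  Z <- check_design(y, post, Z, family)
  n <- length(y)
  n_gamma <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= n_gamma + 2L)
    stop("need more individuals than parameters", call. = FALSE)
  if (var(post$dosage) < 1e-8)
    return(not_estimable_fit("latent", family, n))

  theta <- if (prime) prime_from_dosage(y, post, Z, family)
           else theta_null_start(y, Z, family)

  # expanded design, column-major over genotype blocks g = 0, 1, 2 to match
  # as.vector() on the N x 3 responsibility matrix
  X3 <- cbind(1, rep(0:2, each = n),
              if (!is.null(Z)) Z[rep(seq_len(n), 3L), , drop = FALSE])
  y3 <- rep(y, 3L)
  lp <- base::log(post$probs)
  gaussian <- family == "gaussian"

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  coef_vec <- c(theta$alpha, theta$beta, theta$gamma)
  for (iter in seq_len(max_iter)) {
    eta <- eta_matrix(theta, Z, n)
    lw <- lp + logf_family(y, eta, family, theta$sigma2)
    lse <- log_row_sum_exp(lw)
    ll <- sum(lse)
    trace[iter] <- ll
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    w3 <- as.vector(exp(lw - lse))  # responsibilities, rows sum to 1
    if (gaussian) {
      coef_vec <- drop(wls_solve(X3, y3, w3))
      sigma2 <- sum(w3 * (y3 - drop(X3 %*% coef_vec))^2) / n
      theta <- theta_new(coef_vec[[1]], coef_vec[[2]],
                         gamma = if (n_gamma) coef_vec[-(1:2)] else numeric(0),
                         sigma2 = sigma2)
    } else {
      coef_vec <- wglm_irls(X3, y3, w3, family, start = coef_vec)
      theta <- theta_new(coef_vec[[1]], coef_vec[[2]],
                         gamma = if (n_gamma) coef_vec[-(1:2)] else numeric(0))
    }
  }
  coefficients <- stats::setNames(
    c(theta$alpha, theta$beta, theta$gamma),
    c("alpha", "beta", if (n_gamma) paste0("gamma", seq_len(n_gamma))))

  se_vec <- rep(NA_real_, length(coefficients))
  se_beta <- NA_real_
  if (se) {
    fi <- fisher_se(theta, y, post, Z, family)
    se_vec <- fi$se[seq_along(coefficients)]
    se_beta <- fi$se_beta
  }
  ll_final <- trace[length(trace)]
  if (test == "wald") {
    stat <- (theta$beta / se_beta)^2
    pv <- wald_p(theta$beta, se_beta)
  } else {
    th0 <- null_theta(y, Z, family)
    ll0 <- latent_loglik(th0, y, post, Z, family)
    stat <- 2 * (ll_final - ll0)
    pv <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  new_latent_fit("latent", family, n, theta = theta,
                 coefficients = coefficients, se = se_vec, se_beta = se_beta,
                 loglik = ll_final, loglik_trace = trace, iterations = iter,
                 converged = converged, statistic = stat, pvalue = pv)
}

# null-model MLE packed as a theta with beta = 0; the intercept-only case
# has a closed form (link of the phenotype mean)
null_theta <- function(y, Z, family) {
  if (is.null(Z)) {
    mu <- mean(y)
    alpha <- switch(family,
      gaussian = mu,
      binomial = stats::qlogis(min(max(mu, 1e-12), 1 - 1e-12)),
      poisson = base::log(max(mu, 1e-12)))
    return(theta_new(alpha, 0,
                     sigma2 = if (family == "gaussian") mean((y - mu)^2)))
  }
  X0 <- cbind(rep(1, length(y)), Z)
  fit0 <- glm_basic(X0, y, family)
  theta_new(fit0$coefficients[[1]], 0,
            gamma = if (ncol(X0) > 1) fit0$coefficients[-1] else numeric(0),
            sigma2 = fit0$sigma2)
}

# ---- fast weighted GLM for the M-step ---------------------------------------

# Weighted least squares by normal equations (p is tiny, rows are 3N).
wls_solve <- function(X, y, w) {
  xtwx <- crossprod(X, X * w)
  ch <- tryCatch(chol(xtwx), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-10 * sqrt(max(diag(xtwx)))))
    stop("singular fit: design matrix is collinear", call. = FALSE)
  backsolve(ch, backsolve(ch, crossprod(X, w * y), transpose = TRUE))
}

# Weighted IRLS to inner convergence for binomial/poisson M-steps, with
# step-halving on the weighted log-likelihood.
wglm_irls <- function(X, y, w, family, start, tol = 1e-8, maxit = 100L) {
  beta <- start
  wll <- function(b) {
    eta <- drop(X %*% b)
    sum(w * logf_family(y, eta, family))
  }
  ll <- NULL  # evaluated lazily: step-halving only engages on large steps
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    if (family == "binomial") {
      mu <- plogis(eta)
      v <- pmax(mu * (1 - mu), 1e-12)
      z <- eta + (y - mu) / v
    } else {
      mu <- pmax(exp(eta), 1e-12)
      v <- mu
      z <- eta + (y - mu) / v
    }
    beta_new <- drop(wls_solve(X, z, w * v))
    step <- max(abs(beta_new - beta))
    if (step > 0.5 * (1 + max(abs(beta)))) {
      if (is.null(ll)) ll <- wll(beta)
      ll_new <- wll(beta_new)
      halvings <- 0L
      while ((!is.finite(ll_new) || ll_new < ll - 1e-12) && halvings < 20L) {
        beta_new <- (beta + beta_new) / 2
        ll_new <- wll(beta_new)
        halvings <- halvings + 1L
      }
      ll <- ll_new
    } else {
      ll <- NULL
    }
    done <- step < tol * (1 + max(abs(beta)))
    beta <- drop(beta_new)
    if (done) break
  }
  beta
}

# ---- observed Fisher information --------------------------------------------

# analytic gradient of the marginal log-likelihood at a flattened theta
latent_score_vector <- function(v, y, post, Z, family, n_gamma, has_sigma2,
                                lp = base::log(post$probs)) {
  theta <- unflatten_theta(v, n_gamma, has_sigma2)
  n <- length(y)
  eta <- eta_matrix(theta, Z, n)
  lw <- lp + logf_family(y, eta, family, theta$sigma2)
  w <- exp(lw - log_row_sum_exp(lw))
  dl <- dlogf_deta(y, eta, family, theta$sigma2)
  wd <- w * dl
  g_alpha <- sum(wd)
  g_beta <- sum(wd %*% c(0, 1, 2))
  g_gamma <- if (n_gamma) drop(crossprod(Z, rowSums(wd))) else numeric(0)
  out <- c(g_alpha, g_beta, g_gamma)
  if (has_sigma2) {
    s2 <- theta$sigma2
    dls2 <- -1 / (2 * s2) + (y - eta)^2 / (2 * s2^2)
    out <- c(out, sum(w * dls2))
  }
  out
}

# observed information (minus Hessian) by central differences of the
# analytic gradient; step 1e-5 * max(1, |theta_j|)
observed_information <- function(v, y, post, Z, family, n_gamma, has_sigma2,
                                 lp = base::log(post$probs)) {
  p <- length(v)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(v[j]))
    vp <- v; vp[j] <- v[j] + h
    vm <- v; vm[j] <- v[j] - h
    H[, j] <- (latent_score_vector(vp, y, post, Z, family, n_gamma,
                                   has_sigma2, lp) -
               latent_score_vector(vm, y, post, Z, family, n_gamma,
                                   has_sigma2, lp)) / (2 * h)
  }
  -(H + t(H)) / 2
}

#' Standard errors from the observed Fisher information
#'
#' Standard errors of the latent-model parameter estimates: square roots of
#' the diagonal of the inverse observed information (negative Hessian) of
#' the marginal log-likelihood at the fitted parameters. The Hessian is
#' computed by central finite differences of the analytic score, step
#' `1e-5 * max(1, |theta_j|)`; for the gaussian family `sigma2` is included
#' as a parameter of the information matrix.
#'
#' @param theta fitted theta list (a local maximum), or a `latent_fit`.
#' @inheritParams latent_loglik
#' @return list with `se` (named, one per coefficient, plus `sigma2` for
#'   gaussian), `se_beta`, and the information matrix `info`. If the
#'   information matrix is not positive definite a warning is given and the
#'   SEs are `NA`.
#' @export
fisher_se <- function(theta, y, post, Z = NULL, family = "gaussian") {
  if (inherits(theta, "latent_fit")) theta <- theta$theta
  family <- check_family(family)
  Z <- check_design(y, post, Z, family)
  theta$gamma <- theta$gamma %||% numeric(0)
  n_gamma <- length(theta$gamma)
  has_sigma2 <- family == "gaussian"
  v <- flatten_theta(theta)
  info <- observed_information(v, y, post, Z, family, n_gamma, has_sigma2)
  se <- rep(NA_real_, length(v))
  ok <- FALSE
  ev <- tryCatch(min(eigen(info, symmetric = TRUE,
                           only.values = TRUE)$values),
                 error = function(e) -Inf)
  if (ev > 0) {
    se <- sqrt(diag(solve(info)))
    ok <- TRUE
  } else {
    warning("observed information is not positive definite; SEs set to NA")
  }
  names(se) <- names(v)
  list(se = se, se_beta = if (ok) se[[2]] else NA_real_, info = info)
}

# ---- score test -------------------------------------------------------------

#' Score test for a genotype effect under genotype uncertainty
#'
#' Tests \eqn{\beta = 0} in the latent-genotype GLM without fitting the
#' alternative: the score of the marginal likelihood with respect to
#' \eqn{\beta}, evaluated at the null-model MLE, is standardized by the
#' efficient information (the \eqn{\beta} block of the observed information
#' with the nuisance parameters profiled out; for the gaussian family the
#' residual variance is plugged in at its null MLE). The statistic is
#' referred to \eqn{\chi^2_1}. Because the coefficients are never estimated
#' under the alternative the test is very fast, but no effect size is
#' produced.
#'
#' @inheritParams latent_loglik
#' @return a `latent_fit` object (`method = "score"`) with `statistic` and
#'   `pvalue`; `beta` is not estimated. A site with no posterior dosage
#'   variance returns statistic 0 and p-value 1.
#' @export
score_test <- function(y, post, Z = NULL, family = "gaussian") {
  family <- check_family(family)
  Z <- check_design(y, post, Z, family)
  n <- length(y)
  if (var(post$dosage) < 1e-8)
    return(new_latent_fit("score", family, n, statistic = 0, pvalue = 1,
                          loglik = NA_real_, iterations = 0L,
                          converged = TRUE))
  th0 <- null_theta(y, Z, family)
  # At beta = 0 the linear predictor does not depend on g, so the genotype
  # responsibilities equal the posterior probabilities and both the score
  # and the observed information have closed forms in the posterior moments
  # m1 = E[G], m2 = E[G^2]. The gaussian residual variance is plugged in at
  # its null MLE, so the degenerate-posterior case reduces exactly to the
  # classical Rao statistic.
  eta0 <- rep_len(th0$alpha +
    if (length(th0$gamma)) drop(Z %*% th0$gamma) else 0, n)
  dl <- dlogf_deta(y, eta0, family, th0$sigma2)
  d2l <- switch(family,
    gaussian = rep(-1 / th0$sigma2, n),
    binomial = { mu <- plogis(eta0); -mu * (1 - mu) },
    poisson = -exp(eta0))
  m1 <- post$dosage
  m2 <- post$probs[, 2] + 4 * post$probs[, 3]
  U <- sum(dl * m1)
  # observed information blocks for (beta; alpha, gamma)
  X0 <- cbind(rep(1, n), Z)
  i_bb <- -sum(d2l * m2 + dl^2 * (m2 - m1^2))
  i_bn <- -drop(crossprod(d2l * m1, X0))
  i_nn <- -crossprod(X0, X0 * d2l)
  i_eff <- i_bb - drop(i_bn %*% solve(i_nn, i_bn))
  if (!is.finite(i_eff) || i_eff <= 0)
    return(new_latent_fit("score", family, n, statistic = 0, pvalue = 1,
                          iterations = 0L, converged = TRUE))
  stat <- U^2 / i_eff
  new_latent_fit("score", family, n, statistic = stat,
                 pvalue = pchisq(stat, df = 1, lower.tail = FALSE),
                 loglik = latent_loglik(th0, y, post, Z, family),
                 iterations = 0L, converged = TRUE)
}

#' Hybrid association test: score screen, then EM
#'
#' Combines the speed of the score test with the effect estimates of the
#' EM fit: every site is score-tested, and only sites with score p-value
#' below `screen_alpha` are refitted with the full latent EM (whose
#' estimate, SE and p-value are then reported). Sites failing the screen
#' report the score p-value with no effect estimate. The `branch` field
#' records which path was taken.
#'
#' @inheritParams fit_latent
#' @param screen_alpha score p-value threshold below which the EM fit is run.
#' @return a `latent_fit` object (`method = "hybrid"`).
#' @export
fit_hybrid <- function(y, post, Z = NULL, family = "gaussian",
                       screen_alpha = 0.05, ...) {
  st <- score_test(y, post, Z, family)
  if (is.finite(st$pvalue) && st$pvalue < screen_alpha) {
    fit <- fit_latent(y, post, Z, family, ...)
    fit$method <- "hybrid"
    fit$branch <- "latent"
    fit
  } else {
    st$method <- "hybrid"
    st$branch <- "score"
    st
  }
}

# ---- methods ----------------------------------------------------------------

#' @export
print.latent_fit <- function(x, ...) {
  cat("<latent_fit> method =", x$method, ", family =", x$family,
      ", n =", x$n, "\n")
  if (!x$estimable) {
    cat("  site not estimable (no posterior dosage variance)\n")
    return(invisible(x))
  }
  if (!is.null(x$coefficients)) {
    cat("  beta =", signif(x$coefficients[["beta"]], 6),
        " se =", signif(x$se_beta, 6), "\n")
  }
  cat("  p-value =", format(x$pvalue, digits = 4),
      if (!is.na(x$branch)) paste0(" (branch: ", x$branch, ")"), "\n")
  invisible(x)
}

#' Tidy a latent-model fit
#'
#' @param x a `latent_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per model term with `estimate`, `std.error`,
#'   and for the genotype term the Wald `statistic` and `p.value`.
#'   `glance()`: a one-row model summary.
#' @method tidy latent_fit
#' @export
tidy.latent_fit <- function(x, ...) {
  if (is.null(x$coefficients))
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se[seq_along(x$coefficients)]),
    statistic = ifelse(names(x$coefficients) == "beta", x$statistic,
                       NA_real_),
    p.value = ifelse(names(x$coefficients) == "beta", x$pvalue, NA_real_)
  )
}

#' @rdname tidy.latent_fit
#' @method glance latent_fit
#' @export
glance.latent_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, family = x$family, n = x$n,
    beta = if (!is.null(x$coefficients)) x$coefficients[["beta"]]
           else NA_real_,
    se_beta = x$se_beta, statistic = x$statistic, p.value = x$pvalue,
    logLik = x$loglik, iterations = x$iterations, converged = x$converged,
    estimable = x$estimable, branch = x$branch
  )
}
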