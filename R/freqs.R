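#' Maximum-likelihood sample allele frequency from genotype likelihoods
#'
#' EM estimate of the allele frequency f maximizing the marginal likelihood
#' \eqn{\prod_i \sum_g p(x_i \mid g)\, p(g \mid f)} with the Hardy-Weinberg
#' prior. The update is the posterior mean allele count: \eqn{f \leftarrow
#' \frac{1}{2N} \sum_i E[G_i \mid x_i, f]}. With certain genotypes this
#' reduces exactly to allele counting.
#'
#' @param gl a [genotype_likelihoods] object.
#' @param f0 starting frequency.
#' @param tol convergence tolerance on `|delta f|`.
#' @param max_iter iteration cap.
#' @return An `af_estimate` list: `f`, `loglik`, `loglik_trace`,
#'   `iterations`, `converged`.
#' @export
estimate_sample_af <- function(gl, f0 = 0.25, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  ll <- gl$loglik
  informative <- !(ll[, 1] == ll[, 2] & ll[, 2] == ll[, 3])
  if (!any(informative))
    stop("cannot estimate a frequency: all likelihood rows are constant",
         call. = FALSE)
  n <- nrow(ll)
  f <- f0
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- row_softmax(ll + rep(base::log(hwe_prior_vec(f)), each = n))
    trace[iter] <- sum(base::log(rowSums(exp(ll) * rep(hwe_prior_vec(f),
                                                       each = n))))
    f_new <- mean(w[, 2] + 2 * w[, 3]) / 2
    if (abs(f_new - f) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  structure(list(f = f, loglik = af_loglik(gl, f), loglik_trace = trace,
                 iterations = iter, converged = converged),
            class = "af_estimate")
}

hwe_prior_vec <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)

# marginal log-likelihood of a frequency (or per-individual frequencies)
af_loglik <- function(gl, freq) {
  n <- nrow(gl$loglik)
  pw <- hwe_prior_matrix(rep_len(freq, n))
  sum(base::log(rowSums(exp(gl$loglik) * pw)))
}

#' Population allele frequencies with known admixture proportions
#'
#' EM estimate of the K population allele frequencies F from genotype
#' likelihoods, holding the admixture proportions Q fixed (the
#' NGSadmix-style frequency update with known Q). The model places each
#' individual's genotype under Hardy-Weinberg proportions at its individual
#' allele frequency \eqn{\pi_i = \sum_k q_{ik} F_k}; the M-step attributes
#' each expected allele copy to a population in proportion to
#' \eqn{q_{ik} F_k / \pi_i} (minor) and \eqn{q_{ik}(1-F_k)/(1-\pi_i)}
#' (major). Frequencies are clamped to \[1e-6, 1 - 1e-6\] during iteration
#' to keep the prior non-degenerate; a boundary optimum is reported
#' unclamped.
#'
#' @param gl a [genotype_likelihoods] object.
#' @param Q N x K admixture matrix, rows summing to 1.
#' @param F0 starting frequencies (length K).
#' @param tol convergence tolerance on `max |delta F|`.
#' @param max_iter iteration cap.
#' @return An `af_estimate` list: `F` (length-K vector), `loglik`,
#'   `loglik_trace`, `iterations`, `converged`.
#' @export
estimate_pop_freqs <- function(gl, Q, F0 = NULL, tol = 1e-6,
                               max_iter = 500L) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  Q <- as.matrix(Q)
  n <- nrow(gl$loglik)
  if (nrow(Q) != n) stop("Q must have one row per individual", call. = FALSE)
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("rows of `Q` must sum to 1", call. = FALSE)
  K <- ncol(Q)
  wk <- colSums(Q)
  weightless <- wk < 1e-8 * n
  if (any(weightless))
    warning("population(s) ", paste(which(weightless), collapse = ", "),
            " have ~zero total admixture weight; frequency not identifiable")
  Fk <- rep_len(F0 %||% 0.25, K)
  lik <- exp(gl$loglik)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  for (iter in seq_len(max_iter)) {
    pi_i <- drop(Q %*% Fk)
    pw <- hwe_prior_matrix(pi_i)
    post <- lik * pw
    s <- rowSums(post)
    trace[iter] <- sum(base::log(s))
    d <- (post[, 2] + 2 * post[, 3]) / s        # E[G_i]
    # expected minor/major allele copies attributed to population k
    a_k <- colSums(d * Q * rep(Fk, each = n) / pi_i)
    b_k <- colSums((2 - d) * Q * rep(1 - Fk, each = n) / (1 - pi_i))
    F_new <- clamp(a_k / (a_k + b_k))
    F_new[weightless] <- 0.5
    delta <- max(abs(F_new - Fk))
    Fk <- F_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # report boundary optima unclamped
  F_out <- Fk
  F_out[F_out <= 1e-6 & boundary_better(gl, Q, Fk, 0)] <- 0
  F_out[F_out >= 1 - 1e-6 & boundary_better(gl, Q, Fk, 1)] <- 1
  if (any(weightless)) converged <- FALSE
  structure(list(F = F_out, loglik = sum(base::log(
    rowSums(exp(gl$loglik) * hwe_prior_matrix(drop(Q %*% F_out))))),
    loglik_trace = trace, iterations = iter, converged = converged),
    class = "af_estimate")
}

# would moving a near-boundary frequency onto the boundary not lower loglik?
boundary_better <- function(gl, Q, Fk, bound) {
  vapply(seq_along(Fk), function(k) {
    Fb <- Fk
    Fb[k] <- bound
    ll_b <- af_loglik(gl, drop(Q %*% Fb))
    ll_b >= af_loglik(gl, drop(Q %*% Fk)) - 1e-12
  }, logical(1))
}

#' @export
print.af_estimate <- function(x, ...) {
  if (!is.null(x$f))
    cat("<af_estimate> f =", signif(x$f, 6))
  else
    cat("<af_estimate> F = (", paste(signif(x$F, 6), collapse = ", "), ")")
  cat(", loglik =", signif(x$loglik, 8), ",", x$iterations, "iterations",
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}

#' @method tidy af_estimate
#' @export
tidy.af_estimate <- function(x, ...) {
  if (!is.null(x$f))
    tibble::tibble(population = NA_integer_, estimate = x$f)
  else
    tibble::tibble(population = seq_along(x$F), estimate = x$F)
}

#' @method glance af_estimate
#' @export
glance.af_estimate <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged)
}
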