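#' Genotype likelihoods for one biallelic site
#'
#' Container for per-individual genotype likelihoods \eqn{p(\mathrm{reads}
#' \mid G = g)}, \eqn{g \in \{0, 1, 2\}} copies of the minor allele, at a
#' single biallelic site. Likelihoods are stored in log space; only ratios
#' within a row matter, so rows may be supplied on any positive scale.
#'
#' An individual with sequencing depth 0 carries no information: its
#' likelihood row is constant across genotypes, and its posterior under any
#' prior equals that prior.
#'
#' @param values N x 3 matrix of likelihoods (columns: g = 0, 1, 2). Raw
#'   likelihoods by default; set `log = TRUE` if already on the log scale.
#' @param depth optional integer vector of per-individual read counts. If
#'   omitted, individuals with constant likelihood rows are assigned depth 0
#'   and all others depth `NA`.
#' @param site_id optional marker label.
#' @param log are `values` log-likelihoods?
#'
#' @return An object of class `genotype_likelihoods` with elements
#'   `loglik` (N x 3, row-max-normalized), `depth`, `site_id`.
#' @examples
#' gl <- genotype_likelihoods(rbind(c(1, 0.5, 0.01), c(1, 1, 1)))
#' genotype_posterior(gl, prior_sample_af(0.1))
#' @export
genotype_likelihoods <- function(values, depth = NULL, site_id = NULL,
                                 log = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != 3L)
    stop("`values` must have 3 columns (genotypes 0, 1, 2)", call. = FALSE)
  if (!log) {
    if (any(!is.finite(values)) || any(values < 0))
      stop("likelihoods must be finite and non-negative", call. = FALSE)
    ll <- suppressWarnings(base::log(values))  # zeros -> -Inf is fine
  } else {
    if (any(is.nan(values)) || any(values == Inf))
      stop("log-likelihoods must be finite or -Inf", call. = FALSE)
    ll <- values
  }
  n <- nrow(ll)
  if (is.null(depth)) {
    const <- ll[, 1] == ll[, 2] & ll[, 2] == ll[, 3]
    depth <- ifelse(const, 0L, NA_integer_)
  } else {
    depth <- as.integer(depth)
    if (length(depth) != n)
      stop("`depth` must have one entry per individual", call. = FALSE)
    if (any(depth < 0, na.rm = TRUE))
      stop("`depth` must be non-negative", call. = FALSE)
  }
  # normalize each row by its max so exp() is safe downstream
  m <- pmax(ll[, 1], ll[, 2], ll[, 3])
  ok <- is.finite(m)
  ll[ok, ] <- ll[ok, , drop = FALSE] - m[ok]
  structure(list(loglik = unname(ll), depth = depth, site_id = site_id),
            class = "genotype_likelihoods")
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat("<genotype_likelihoods> ", nrow(x$loglik), " individuals",
      if (!is.null(x$site_id)) paste0(", site ", x$site_id), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname genotype_likelihoods
n_individuals <- function(x) UseMethod("n_individuals")

#' @export
n_individuals.genotype_likelihoods <- function(x) nrow(x$loglik)

#' @export
n_individuals.genotype_posterior <- function(x) nrow(x$probs)

#' @method as_tibble genotype_likelihoods
#' @export
as_tibble.genotype_likelihoods <- function(x, ...) {
  tibble::tibble(
    individual = seq_len(nrow(x$loglik)),
    depth = x$depth,
    loglik0 = x$loglik[, 1], loglik1 = x$loglik[, 2], loglik2 = x$loglik[, 3]
  )
}

#' Hardy-Weinberg genotype prior
#'
#' Genotype distribution implied by an allele frequency under
#' Hardy-Weinberg equilibrium: \eqn{((1-f)^2,\; 2f(1-f),\; f^2)}.
#'
#' @param freq allele frequency (scalar or vector) in \[0, 1\].
#' @return For a scalar, a length-3 probability vector; for a vector of
#'   length N, an N x 3 matrix with one row per frequency.
#' @examples
#' hwe_prior(0.1) # c(0.81, 0.18, 0.01)
#' @export
hwe_prior <- function(freq) {
  if (any(!is.finite(freq)) || any(freq < 0) || any(freq > 1))
    stop("`freq` must lie in [0, 1]", call. = FALSE)
  out <- cbind((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  if (length(freq) == 1L) drop(out) else unname(out)
}

#' Individual allele frequencies from admixture proportions
#'
#' For a structured sample with K ancestral populations, the individual
#' allele frequency is the admixture-weighted average of the population
#' frequencies: \eqn{\pi_i = \sum_k q_{ik} f_k}.
#'
#' @param Q N x K admixture-proportion matrix; rows must sum to 1
#'   (tolerance 1e-6).
#' @param F_pop length-K vector of population allele frequencies in \[0, 1\].
#' @return length-N vector of individual allele frequencies.
#' @examples
#' individual_allele_frequency(rbind(c(1, 0), c(0.5, 0.5)), c(0.9, 0.1))
#' @export
individual_allele_frequency <- function(Q, F_pop) {
  Q <- as.matrix(Q)
  if (ncol(Q) != length(F_pop))
    stop("ncol(Q) must equal length(F_pop)", call. = FALSE)
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop("rows of `Q` must sum to 1", call. = FALSE)
  if (any(F_pop < 0 | F_pop > 1))
    stop("population frequencies must lie in [0, 1]", call. = FALSE)
  drop(Q %*% F_pop)
}

#' Genotype priors
#'
#' A prior on the (unobserved) genotype, parameterized by an allele
#' frequency and Hardy-Weinberg proportions. `prior_sample_af()` uses one
#' sample-wide frequency, appropriate for a homogeneous population;
#' `prior_individual_af()` uses per-individual frequencies, typically
#' admixture-weighted population frequencies from
#' [individual_allele_frequency()], appropriate under population structure.
#'
#' @param f sample allele frequency in \[0, 1\].
#' @param pi vector of individual allele frequencies in \[0, 1\], or an
#'   admixture matrix `Q` together with population frequencies `F_pop`.
#' @param Q,F_pop alternative to `pi`: compute it as `Q %*% F_pop`.
#' @return An object of class `genotype_prior`.
#' @examples
#' prior_sample_af(0.45)
#' prior_individual_af(Q = rbind(c(1, 0), c(0.2, 0.8)), F_pop = c(0.9, 0.1))
#' @export
prior_sample_af <- function(f) {
  if (length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("`f` must be a single frequency in [0, 1]", call. = FALSE)
  structure(list(kind = "sample_af", f = f), class = "genotype_prior")
}

#' @rdname prior_sample_af
#' @export
prior_individual_af <- function(pi = NULL, Q = NULL, F_pop = NULL) {
  if (is.null(pi)) {
    if (is.null(Q) || is.null(F_pop))
      stop("supply `pi`, or both `Q` and `F_pop`", call. = FALSE)
    pi <- individual_allele_frequency(Q, F_pop)
  }
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop("individual frequencies must lie in [0, 1]", call. = FALSE)
  structure(list(kind = "individual_af", pi = pi), class = "genotype_prior")
}

#' @export
print.genotype_prior <- function(x, ...) {
  if (x$kind == "sample_af")
    cat("<genotype_prior> sample allele frequency f =", x$f, "\n")
  else
    cat("<genotype_prior> individual allele frequencies, N =",
        length(x$pi), "\n")
  invisible(x)
}

# per-individual prior frequency vector for N individuals
prior_freq_vector <- function(prior, n) {
  stopifnot(inherits(prior, "genotype_prior"))
  if (prior$kind == "sample_af") rep(prior$f, n)
  else {
    if (length(prior$pi) != n)
      stop("prior has ", length(prior$pi), " individuals, data has ", n,
           call. = FALSE)
    prior$pi
  }
}

#' Genotype posteriors from likelihoods and a frequency prior
#'
#' Applies Bayes' rule per individual: the posterior genotype probability is
#' proportional to the genotype likelihood times the Hardy-Weinberg prior at
#' that individual's prior frequency, normalized over \eqn{g \in \{0,1,2\}}.
#' Computation is in log space with max-subtraction, so deep-coverage
#' likelihood rows do not underflow. Individuals with no reads (constant
#' likelihood row) recover the prior exactly.
#'
#' @param gl a [genotype_likelihoods] object, or a posterior-probability
#'   matrix for [genotype_posterior_from_probs()].
#' @param prior a [genotype_prior][prior_sample_af].
#' @return An object of class `genotype_posterior`: `probs` (N x 3 rows
#'   summing to 1), `dosage` (`probs[,2] + 2*probs[,3]`), `depth`,
#'   `freq` (the per-individual prior frequency used).
#' @examples
#' gl <- genotype_likelihoods(rbind(c(1, 1, 1), c(1, 0, 0)))
#' post <- genotype_posterior(gl, prior_sample_af(0.1))
#' dosage(post)
#' @export
genotype_posterior <- function(gl, prior) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  n <- nrow(gl$loglik)
  if (any(!is.finite(pmax(gl$loglik[, 1], gl$loglik[, 2], gl$loglik[, 3]))))
    stop("degenerate site: an individual has all-zero likelihoods",
         call. = FALSE)
  freq <- prior_freq_vector(prior, n)
  lp <- gl$loglik + base::log(hwe_prior_matrix(freq))
  probs <- row_softmax(lp)
  new_genotype_posterior(probs, depth = gl$depth, freq = freq)
}

# hwe_prior that always returns a matrix
hwe_prior_matrix <- function(freq) {
  cbind((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
}

row_softmax <- function(lp) {
  m <- pmax(lp[, 1], lp[, 2], lp[, 3])
  if (any(!is.finite(m)))
    stop("posterior undefined: a row has zero total mass", call. = FALSE)
  e <- exp(lp - m)
  e / rowSums(e)
}

new_genotype_posterior <- function(probs, depth = NULL, freq = NULL) {
  probs <- unname(as.matrix(probs))
  structure(
    list(probs = probs,
         dosage = probs[, 2] + 2 * probs[, 3],
         depth = depth %||% rep(NA_integer_, nrow(probs)),
         freq = freq),
    class = "genotype_posterior"
  )
}

#' @rdname genotype_posterior
#' @param probs N x 3 matrix of genotype probabilities (e.g. read from a
#'   BEAGLE file); rows are renormalized to sum to 1.
#' @param depth optional read-depth vector.
#' @export
genotype_posterior_from_probs <- function(probs, depth = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L || any(probs < 0) || any(!is.finite(probs)))
    stop("`probs` must be a non-negative N x 3 matrix", call. = FALSE)
  s <- rowSums(probs)
  if (any(s <= 0))
    stop("each probability row must have positive mass", call. = FALSE)
  new_genotype_posterior(probs / s, depth = depth)
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat("<genotype_posterior> ", nrow(x$probs), " individuals, mean dosage ",
      signif(mean(x$dosage), 4), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble genotype_posterior
#' @export
as_tibble.genotype_posterior <- function(x, ...) {
  tibble::tibble(
    individual = seq_len(nrow(x$probs)),
    p0 = x$probs[, 1], p1 = x$probs[, 2], p2 = x$probs[, 3],
    dosage = x$dosage, depth = x$depth
  )
}

#' Genotype dosage (expected genotype)
#'
#' The dosage is the posterior mean genotype
#' \eqn{E[G] = p(G{=}1) + 2\,p(G{=}2)}, the scalar summary used by
#' dosage-based association tests.
#'
#' @param post a [genotype_posterior] object.
#' @return numeric vector in \[0, 2\].
#' @export
dosage <- function(post) {
  stopifnot(inherits(post, "genotype_posterior"))
  post$dosage
}

#' MACH-style imputation info measure (R^2)
#'
#' Ratio of the observed variance of the dosages to the binomial variance
#' \eqn{2f(1-f)} expected under Hardy-Weinberg equilibrium, as used by the
#' MACH imputation software. Near 1 when genotypes are predicted with
#' certainty; lower when sequencing depth (or imputation quality) is poor.
#' The empirical variance uses the N-1 denominator.
#'
#' @param dosages numeric vector of dosages (length >= 2), or a
#'   [genotype_posterior].
#' @param freq allele frequency in (0, 1).
#' @return scalar info measure.
#' @examples
#' info_measure(c(0, 1, 1, 2), 0.5) # 4/3
#' @export
info_measure <- function(dosages, freq) {
  if (inherits(dosages, "genotype_posterior")) dosages <- dosages$dosage
  if (length(dosages) < 2L)
    stop("need at least two individuals", call. = FALSE)
  if (!is.finite(freq) || freq <= 0 || freq >= 1)
    stop("`freq` must lie strictly inside (0, 1)", call. = FALSE)
  stats::var(dosages) / (2 * freq * (1 - freq))
}

#' Simulate genotype likelihoods from known genotypes
#'
#' Generates sequencing-read data for one biallelic site under the standard
#' biallelic model: individual i receives \eqn{d_i \sim
#' \mathrm{Poisson}(\lambda_i)} reads, and each read reports the minor
#' allele with probability \eqn{g/2\,(1-\epsilon) + (1 - g/2)\,\epsilon}
#' given genotype g and per-read error rate \eqn{\epsilon}. The genotype
#' likelihood is the product over reads of the per-read probability under
#' each candidate genotype (binomial kernel; the binomial coefficient is
#' constant across genotypes and dropped).
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param genotypes integer vector in \{0, 1, 2\}.
#' @param mean_depth positive mean read depth, scalar or per-individual.
#' @param error_rate per-read error probability, in (0, 0.5).
#' @param site_id optional marker label.
#' @return a [genotype_likelihoods] object whose `depth` holds the simulated
#'   read counts.
#' @export
simulate_genotype_likelihoods <- function(genotypes, mean_depth,
                                          error_rate = 0.01,
                                          site_id = NULL) {
  if (any(!genotypes %in% 0:2))
    stop("`genotypes` must be 0, 1 or 2", call. = FALSE)
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("`error_rate` must be in (0, 0.5)", call. = FALSE)
  n <- length(genotypes)
  lambda <- rep_len(mean_depth, n)
  if (any(lambda <= 0)) stop("`mean_depth` must be positive", call. = FALSE)
  depth <- stats::rpois(n, lambda)
  p_true <- genotypes / 2 * (1 - error_rate) + (1 - genotypes / 2) * error_rate
  minor <- stats::rbinom(n, depth, p_true)
  genotype_likelihoods_from_reads(depth, minor, error_rate, site_id = site_id)
}

#' @rdname simulate_genotype_likelihoods
#' @param depth read count per individual.
#' @param minor_reads number of reads carrying the minor allele.
#' @export
genotype_likelihoods_from_reads <- function(depth, minor_reads,
                                            error_rate = 0.01,
                                            site_id = NULL) {
  p_g <- c(error_rate, 0.5, 1 - error_rate)  # P(minor read | g)
  ll <- vapply(p_g, function(p) {
    minor_reads * base::log(p) + (depth - minor_reads) * base::log(1 - p)
  }, numeric(length(depth)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  genotype_likelihoods(ll, depth = depth, site_id = site_id, log = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
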