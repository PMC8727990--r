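#' Simulation scenario configurations
#'
#' Builds the configuration for a single-site cohort simulation with a
#' quantitative (or binary) phenotype, optional two-population admixture
#' structure and optional correlation between sequencing depth and
#' phenotype. Six named presets (`"scenario1"` .. `"scenario6"`) cover the
#' standard grid: allele frequency 0.45 without structure or population
#' frequencies (0.9, 0.1) with structure, N = 1000, phenotype mean 0,
#' `beta * g`, `q * gamma` or `beta * g + q * gamma` with unit ancestry
#' effect (`gamma = 1`), and depth either independent of the phenotype
#' (`delta = 0`) or correlated with it (`delta > 0`).
#'
#' Under structure, each individual's ancestry proportion for population 1
#' is drawn uniformly on \[0, 1\] and the genotype is Binomial(2, pi) at
#' the admixture-weighted individual allele frequency. Sequencing depth per
#' individual is a two-level design (`depth_levels`, default 1X and 4X)
#' assigned by [assign_depth()].
#'
#' @param scenario optional preset name `"scenario1"` .. `"scenario6"`.
#' @param n cohort size.
#' @param allele_freq scalar frequency, or length-2 population frequencies
#'   when `structured`.
#' @param structured two-population admixture structure?
#' @param beta genotype effect size.
#' @param gamma ancestry effect size (population-1 proportion).
#' @param delta depth-phenotype correlation strength in \[0, 1\].
#' @param depth_levels `(low_mean, high_mean)` mean depths.
#' @param error_rate per-read error probability.
#' @param family `"gaussian"` or `"binomial"`.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = NULL, n = 1000L, allele_freq = 0.45,
                            structured = FALSE, beta = 0, gamma = 0,
                            delta = 0, depth_levels = c(1, 4),
                            error_rate = 0.01, family = "gaussian") {
  if (!is.null(scenario)) {
    presets <- list(
      scenario1 = list(allele_freq = 0.45, structured = FALSE, beta = 0,
                       gamma = 0, delta = 0.5),
      scenario2 = list(allele_freq = 0.45, structured = FALSE, beta = 0.3,
                       gamma = 0, delta = 0),
      scenario3 = list(allele_freq = c(0.9, 0.1), structured = TRUE,
                       beta = 0, gamma = 1, delta = 0.5),
      scenario4 = list(allele_freq = c(0.9, 0.1), structured = TRUE,
                       beta = 0.3, gamma = 1, delta = 0),
      scenario5 = list(allele_freq = 0.45, structured = FALSE, beta = 0.3,
                       gamma = 0, delta = 0.5),
      scenario6 = list(allele_freq = c(0.9, 0.1), structured = TRUE,
                       beta = 0.3, gamma = 1, delta = 0.5)
    )
    if (!scenario %in% names(presets))
      stop("unknown scenario preset: ", scenario, call. = FALSE)
    p <- presets[[scenario]]
    miss <- setdiff(names(p), names(match.call())[-1])
    for (nm in miss) assign(nm, p[[nm]])
  }
  if (structured && length(allele_freq) != 2L)
    stop("structured scenarios need 2 population frequencies", call. = FALSE)
  if (!structured && length(allele_freq) != 1L)
    stop("unstructured scenarios need a scalar frequency", call. = FALSE)
  if (delta < 0 || delta > 1) stop("`delta` must be in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), allele_freq = allele_freq,
                 structured = structured, beta = beta, gamma = gamma,
                 delta = delta, depth_levels = depth_levels,
                 error_rate = error_rate,
                 family = check_family(family), scenario = scenario),
            class = c("scenario_config", "sim_config"))
}

#' Case-control simulation configuration
#'
#' Configuration for a large case-control design with a multiplicative
#' per-allele relative risk and differential sequencing depth between cases
#' and controls. The defaults reproduce the standard design: 50,000 cases
#' at mean depth 4X and 50,000 controls at 1X, causal allele frequency
#' 0.05, disease prevalence 0.10. Presets `"table2"` (zero-read individuals
#' removed) and `"table3"` (retained) differ only in `drop_zero_depth`.
#'
#' The per-genotype disease risk is \eqn{p(\mathrm{case} \mid g) = k\,
#' \mathrm{RR}^g} with baseline k solved so that the population prevalence
#' matches under Hardy-Weinberg genotype proportions; case and control
#' genotypes are drawn from the corresponding conditional distributions.
#'
#' @param preset optional `"table2"` or `"table3"`.
#' @param n_cases,n_controls stratum sizes.
#' @param causal_freq causal (minor) allele frequency.
#' @param prevalence population disease prevalence.
#' @param rr per-allele relative risk.
#' @param depth_cases,depth_controls mean sequencing depths.
#' @param drop_zero_depth remove individuals with zero reads?
#' @param error_rate per-read error probability.
#' @return a `case_control_config` list.
#' @export
case_control_config <- function(preset = NULL, n_cases = 50000L,
                                n_controls = 50000L, causal_freq = 0.05,
                                prevalence = 0.10, rr = 1.1,
                                depth_cases = 4, depth_controls = 1,
                                drop_zero_depth = TRUE, error_rate = 0.01) {
  if (!is.null(preset)) {
    if (!preset %in% c("table2", "table3"))
      stop("unknown preset: ", preset, call. = FALSE)
    drop_zero_depth <- preset == "table2"
  }
  dist <- case_control_genotype_dist(rr, causal_freq, prevalence)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal_freq = causal_freq, prevalence = prevalence, rr = rr,
                 depth_cases = depth_cases, depth_controls = depth_controls,
                 drop_zero_depth = drop_zero_depth, error_rate = error_rate,
                 family = "binomial", genotype_dist = dist, preset = preset),
            class = c("case_control_config", "sim_config"))
}

#' Genotype distributions in cases and controls under a relative risk
#'
#' Closed-form conditional genotype distributions for the case-control
#' design: with Hardy-Weinberg proportions `hwe(f)` and per-genotype risk
#' \eqn{k\,\mathrm{RR}^g}, `p(g | case)` is proportional to
#' `hwe(f)_g * RR^g` and `p(g | control)` to `hwe(f)_g * (1 - k RR^g)`.
#'
#' @param rr per-allele relative risk.
#' @param f causal allele frequency.
#' @param prevalence disease prevalence.
#' @return list with `case`, `control` (length-3 probability vectors),
#'   per-genotype `risk`, and the baseline risk `k`.
#' @export
case_control_genotype_dist <- function(rr, f, prevalence) {
  hwe <- hwe_prior(f)
  k <- prevalence / sum(hwe * rr^(0:2))
  risk <- k * rr^(0:2)
  if (any(risk >= 1))
    stop("per-genotype risk exceeds 1; lower `rr` or `prevalence`",
         call. = FALSE)
  list(case = hwe * risk / prevalence,
       control = hwe * (1 - risk) / (1 - prevalence),
       risk = risk, k = k)
}

#' Two-level sequencing depth with phenotype correlation
#'
#' Assigns each individual a low or high mean sequencing depth. With
#' correlation strength `delta`, an individual in the top half of the
#' phenotype ranking (or a case, for a 0/1 phenotype) is placed in the
#' high-depth group with probability `0.5 + delta/2`, and otherwise with
#' probability `0.5 - delta/2`. `delta = 0` is an independent coin flip;
#' `delta = 1` splits deterministically. Uses the session RNG.
#'
#' @param x phenotype values or 0/1 case status.
#' @param delta correlation strength in \[0, 1\].
#' @param depth_levels `(low_mean, high_mean)`.
#' @return numeric vector of per-individual mean depths.
#' @export
assign_depth <- function(x, delta, depth_levels = c(1, 4)) {
  if (delta < 0 || delta > 1) stop("`delta` must be in [0, 1]", call. = FALSE)
  n <- length(x)
  high_prone <- if (all(x %in% c(0, 1))) x == 1
                else rank(x, ties.method = "first") > n / 2
  p_high <- ifelse(high_prone, 0.5 + delta / 2, 0.5 - delta / 2)
  high <- stats::rbinom(n, 1L, p_high) == 1L
  ifelse(high, depth_levels[2], depth_levels[1])
}

new_sim_cohort <- function(genotypes, phenotype, gl, depth_mean, truth,
                           Q = NULL, pi = NULL) {
  structure(list(genotypes = genotypes, phenotype = phenotype, gl = gl,
                 depth = gl$depth, depth_mean = depth_mean, Q = Q, pi = pi,
                 truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(x$phenotype), " individuals, mean depth ",
      signif(mean(x$depth), 3),
      if (!is.null(x$Q)) ", structured", "\n", sep = "")
  invisible(x)
}

#' @method as_tibble sim_cohort
#' @export
as_tibble.sim_cohort <- function(x, ...) {
  tb <- tibble::tibble(individual = seq_along(x$phenotype),
                       genotype = x$genotypes, phenotype = x$phenotype,
                       depth = x$depth, depth_mean = x$depth_mean)
  if (!is.null(x$Q)) {
    tb$q1 <- x$Q[, 1]
    tb$pi <- x$pi
  }
  tb
}

# subset every per-individual field of a cohort
subset_cohort <- function(cohort, keep) {
  gl <- cohort$gl
  gl2 <- genotype_likelihoods(gl$loglik[keep, , drop = FALSE],
                              depth = gl$depth[keep],
                              site_id = gl$site_id, log = TRUE)
  new_sim_cohort(cohort$genotypes[keep], cohort$phenotype[keep], gl2,
                 cohort$depth_mean[keep], cohort$truth,
                 Q = if (!is.null(cohort$Q)) cohort$Q[keep, , drop = FALSE],
                 pi = cohort$pi[keep])
}

#' Simulate a cohort at a single biallelic site
#'
#' Draws genotypes, phenotype, per-individual sequencing depth and read
#' data for one site under a [scenario_config()] or
#' [case_control_config()].
#'
#' For a scenario config: under structure, ancestry proportions
#' `Q[,1] ~ U(0,1)`, individual allele frequencies `pi = Q %*% F`, genotype
#' `Binomial(2, pi)`; the quantitative phenotype is normal with mean
#' `beta*g + gamma*q` and SD 1 (a binary phenotype uses a logistic model
#' with the same linear predictor). Depth follows [assign_depth()] and
#' reads follow [simulate_genotype_likelihoods()].
#'
#' For a case-control config: genotypes are drawn from the closed-form
#' case/control conditional distributions
#' ([case_control_genotype_dist()]), cases get mean depth `depth_cases` and
#' controls `depth_controls`, and zero-read individuals are removed when
#' `drop_zero_depth` is set.
#'
#' @param cfg a `scenario_config` or `case_control_config`.
#' @param seed optional integer seed (set once at entry).
#' @return a `sim_cohort`: `genotypes`, `phenotype`, `gl`
#'   ([genotype_likelihoods]), `depth`, `depth_mean`, `Q`/`pi` when
#'   structured, and `truth` (the generating config).
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  UseMethod("simulate_cohort")
}

#' @export
simulate_cohort.scenario_config <- function(cfg, seed = NULL) {
  n <- cfg$n
  if (cfg$structured) {
    q1 <- stats::runif(n)
    Q <- cbind(q1, 1 - q1, deparse.level = 0)
    pi_i <- individual_allele_frequency(Q, cfg$allele_freq)
  } else {
    Q <- NULL
    pi_i <- rep(cfg$allele_freq, n)
  }
  g <- stats::rbinom(n, 2L, pi_i)
  lin <- cfg$beta * g + if (cfg$structured) cfg$gamma * Q[, 1] else 0
  y <- if (cfg$family == "gaussian") stats::rnorm(n, lin, 1)
       else stats::rbinom(n, 1L, plogis(lin))
  depth_mean <- assign_depth(y, cfg$delta, cfg$depth_levels)
  gl <- simulate_genotype_likelihoods(g, depth_mean, cfg$error_rate)
  new_sim_cohort(g, y, gl, depth_mean, cfg, Q = Q, pi = pi_i)
}

#' @rdname simulate_cohort
#' @export
simulate_case_control <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "case_control_config"))
  if (!is.null(seed)) set.seed(seed)
  simulate_cohort.case_control_config(cfg)
}

#' @export
simulate_cohort.case_control_config <- function(cfg, seed = NULL) {
  dist <- cfg$genotype_dist
  g <- c(sample.int(3L, cfg$n_cases, replace = TRUE, prob = dist$case),
         sample.int(3L, cfg$n_controls, replace = TRUE,
                    prob = dist$control)) - 1L
  y <- rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls))
  depth_mean <- rep(c(cfg$depth_cases, cfg$depth_controls),
                    c(cfg$n_cases, cfg$n_controls))
  gl <- simulate_genotype_likelihoods(g, depth_mean, cfg$error_rate)
  cohort <- new_sim_cohort(g, y, gl, depth_mean, cfg)
  if (cfg$drop_zero_depth) cohort <- subset_cohort(cohort, gl$depth > 0L)
  cohort
}

# population-level logistic slope implied by a case-control config: the
# logistic projection of the exact joint (y, g) cell probabilities; the
# case:control sampling ratio moves only the intercept, not the slope
cc_true_beta <- function(cfg) {
  dist <- cfg$genotype_dist
  w <- c(dist$case, dist$control) / 2
  y <- rep(c(1, 0), each = 3L)
  g <- rep(0:2, 2L)
  fit <- glm_basic(cbind(1, g), y, "binomial", weights = w * 1e6)
  fit$coefficients[[2]]
}

true_beta_of <- function(cfg) {
  if (inherits(cfg, "case_control_config")) cc_true_beta(cfg) else cfg$beta
}

# sample-level "true" prior frequency for a config
true_prior_freq <- function(cfg, cohort) {
  if (inherits(cfg, "case_control_config")) cfg$causal_freq
  else if (cfg$structured) mean(cohort$pi)
  else cfg$allele_freq
}

# build the posterior for a cohort under one prior spec
cohort_posterior <- function(cohort, prior_spec) {
  cfg <- cohort$truth
  switch(prior_spec,
    sample_true = genotype_posterior(
      cohort$gl, prior_sample_af(true_prior_freq(cfg, cohort))),
    sample_estimated = genotype_posterior(
      cohort$gl, prior_sample_af(estimate_sample_af(cohort$gl)$f)),
    individual_true = {
      if (is.null(cohort$Q)) stop("individual prior needs structure",
                                  call. = FALSE)
      genotype_posterior(cohort$gl, prior_individual_af(cohort$pi))
    },
    individual_estimated = {
      if (is.null(cohort$Q)) stop("individual prior needs structure",
                                  call. = FALSE)
      Fh <- estimate_pop_freqs(cohort$gl, cohort$Q)$F
      genotype_posterior(cohort$gl,
                         prior_individual_af(Q = cohort$Q, F_pop = Fh))
    },
    stop("unknown prior spec: ", prior_spec, call. = FALSE)
  )
}

# true-genotype GLM; aggregates the covariate-free binary case into 3 cells
fit_true_genotype <- function(y, g, Z, family) {
  n <- length(y)
  if (family == "binomial" && is.null(Z)) {
    # aggregate into the 3 genotype cells: identical MLE and SEs, much faster
    tab <- table(factor(y, levels = c(0, 1)), factor(g, levels = 0:2))
    tot <- colSums(tab)
    keep <- tot > 0
    succ <- tab[2, keep]
    fit <- glm_basic(cbind(1, (0:2)[keep]), unname(succ / tot[keep]), family,
                     weights = unname(tot[keep]))
  } else {
    fit <- glm_basic(cbind(1, g, Z), y, family)
  }
  beta <- fit$coefficients[[2]]
  se_b <- fit$se[[2]]
  new_latent_fit("true", family, n,
                 coefficients = stats::setNames(
                   fit$coefficients[1:2], c("alpha", "beta")),
                 se = fit$se, se_beta = se_b, loglik = fit$loglik,
                 iterations = 1L, converged = TRUE,
                 statistic = (beta / se_b)^2, pvalue = wald_p(beta, se_b))
}

#' Power / false-positive-rate / bias experiment
#'
#' Replicates a single-site simulation under `cfg`, runs the requested
#' association methods on each replicate, and summarizes empirical power
#' (fraction of replicates with p-value at or below `alpha`), mean effect
#' estimate and bias, mean standard error, convergence counts and
#' depth-stratified info measures. Per-replicate seeds are derived
#' deterministically from `seed`, so results are reproducible bit-for-bit
#' and methods are compared on identical replicate data (paired).
#'
#' @param cfg a [scenario_config()] or [case_control_config()].
#' @param n_replicates number of simulated sites.
#' @param methods subset of `"true"` (GLM on the true genotypes),
#'   `"dosage"`, `"latent"`, `"score"`, `"hybrid"`.
#' @param priors prior specifications for the posterior-based methods:
#'   subset of `"sample_true"`, `"sample_estimated"`, `"individual_true"`,
#'   `"individual_estimated"` (individual priors require a structured
#'   scenario).
#' @param alpha significance threshold.
#' @param seed master seed.
#' @param adjust_ancestry include the population-1 admixture proportion as
#'   a covariate in structured scenarios.
#' @param screen_alpha hybrid score screen threshold.
#' @param keep_details attach the per-replicate tibble as attribute
#'   `"details"`.
#' @return a `power_result` tibble: one row per method x prior with columns
#'   `power`, `mean_beta`, `bias`, `mean_se`, `sd_beta`, `n_tested`,
#'   `n_converged`, `n_failed`, `mean_r2_high`, `mean_r2_low` (case/control
#'   strata for case-control designs, depth strata otherwise).
#' @export
run_power_experiment <- function(cfg, n_replicates, methods = c("true",
                                   "dosage", "latent"),
                                 priors = "sample_true", alpha = 1e-5,
                                 seed = 1L, adjust_ancestry = TRUE,
                                 screen_alpha = 0.05,
                                 keep_details = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  methods <- match.arg(methods,
    c("true", "dosage", "latent", "score", "hybrid"), several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  post_methods <- setdiff(methods, "true")
  cc <- inherits(cfg, "case_control_config")
  beta_true <- true_beta_of(cfg)

  one_rep <- function(r) {
    cohort <- simulate_cohort(cfg, seed = rep_seeds[r])
    y <- cohort$phenotype
    Z <- if (!is.null(cohort$Q) && adjust_ancestry)
      cohort$Q[, 1, drop = FALSE] else NULL
    rows <- list()
    if ("true" %in% methods) {
      f <- tryCatch(fit_true_genotype(y, cohort$genotypes, Z,
                                      cohort$truth$family),
                    error = function(e) NULL)
      rows[["true"]] <- fit_row(f, r, "true", NA_character_,
                                NA_real_, NA_real_)
    }
    for (pr in if (length(post_methods)) priors else character(0)) {
      post <- tryCatch(cohort_posterior(cohort, pr), error = function(e) NULL)
      if (is.null(post)) next
      fq <- true_prior_freq(cfg, cohort)
      strat <- if (cc) y == 1 else cohort$depth_mean == max(cohort$depth_mean)
      r2_high <- tryCatch(info_measure(post$dosage[strat], fq),
                          error = function(e) NA_real_)
      r2_low <- tryCatch(info_measure(post$dosage[!strat], fq),
                         error = function(e) NA_real_)
      for (m in post_methods) {
        f <- tryCatch(switch(m,
          dosage = fit_dosage(y, post, Z, cohort$truth$family),
          latent = fit_latent(y, post, Z, cohort$truth$family),
          score = score_test(y, post, Z, cohort$truth$family),
          hybrid = fit_hybrid(y, post, Z, cohort$truth$family,
                              screen_alpha = screen_alpha)),
          error = function(e) NULL)
        rows[[paste(m, pr, sep = ".")]] <- fit_row(f, r, m, pr, r2_high,
                                                   r2_low)
      }
    }
    dplyr::bind_rows(rows)
  }
  details <- dplyr::bind_rows(lapply(seq_len(n_replicates), one_rep))

  summ <- details |>
    dplyr::group_by(.data$method, .data$prior) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_tested = sum(!is.na(.data$pvalue)),
      n_converged = sum(!is.na(.data$converged) & .data$converged),
      n_failed = sum(.data$failed),
      power = mean(.data$pvalue[!is.na(.data$pvalue)] <= alpha),
      mean_beta = mean(.data$beta, na.rm = TRUE),
      sd_beta = stats::sd(.data$beta, na.rm = TRUE),
      mean_se = mean(.data$se, na.rm = TRUE),
      mean_r2_high = mean(.data$r2_high, na.rm = TRUE),
      mean_r2_low = mean(.data$r2_low, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(bias = .data$mean_beta - beta_true,
                  true_beta = beta_true, alpha = alpha)
  class(summ) <- c("power_result", class(summ))
  if (keep_details) attr(summ, "details") <- details
  summ
}

fit_row <- function(fit, replicate, method, prior, r2_high, r2_low) {
  if (is.null(fit)) {
    return(tibble::tibble(replicate = replicate, method = method,
                          prior = prior, beta = NA_real_, se = NA_real_,
                          pvalue = NA_real_, converged = NA,
                          iterations = NA_integer_, branch = NA_character_,
                          failed = TRUE, r2_high = r2_high, r2_low = r2_low))
  }
  beta <- if (!is.null(fit$coefficients) && "beta" %in%
              names(fit$coefficients)) fit$coefficients[["beta"]]
          else NA_real_
  tibble::tibble(replicate = replicate, method = method, prior = prior,
                 beta = beta, se = fit$se_beta, pvalue = fit$pvalue,
                 converged = fit$converged, iterations = fit$iterations,
                 branch = fit$branch, failed = FALSE,
                 r2_high = r2_high, r2_low = r2_low)
}

#' Plot a power experiment summary
#'
#' Bar chart of empirical power by method (and prior, if several).
#'
#' @param object a `power_result` from [run_power_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot power_result
#' @export
autoplot.power_result <- function(object, ...) {
  df <- dplyr::mutate(object,
    label = ifelse(is.na(.data$prior), .data$method,
                   paste(.data$method, .data$prior, sep = "\n")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$power)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = paste0("power (alpha = ",
                                       format(df$alpha[1]), ")")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot power curves across effect sizes
#'
#' Line plot of power against effect size for several bound
#' `power_result` tibbles (rows must carry an `effect` column, e.g. added
#' with `dplyr::mutate()` before binding).
#'
#' @param results a tibble of stacked power results with an `effect`
#'   column.
#' @return a ggplot object.
#' @export
plot_power_curves <- function(results) {
  stopifnot("effect" %in% names(results))
  df <- dplyr::mutate(results,
    label = ifelse(is.na(.data$prior), .data$method,
                   paste(.data$method, .data$prior, sep = ", ")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$power,
                                   colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "effect size", y = "power", colour = NULL) +
    ggplot2::theme_minimal()
}
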