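#' Read a BEAGLE genotype-probability file
#'
#' Parses the ANGSD-style BEAGLE text format: a whitespace-separated table
#' with header columns `marker allele1 allele2` followed by three columns
#' per individual holding the genotype probabilities (or scaled genotype
#' likelihoods) for 0, 1 and 2 copies of the second allele. Gzipped files
#' are read transparently. Each per-individual triplet must sum to 1 within
#' `tol` and is renormalized on load; ragged rows, non-numeric entries and
#' badly mis-summing triplets are parse errors reported with their line
#' number.
#'
#' @param path file path (optionally `.gz`).
#' @param tol allowed deviation of triplet sums from 1 (default 0.1, i.e.
#'   sums in \[0.9, 1.1\]).
#' @return a `beagle_table`: tibble with columns `marker`, `allele1`,
#'   `allele2` and a list-column `probs` of N x 3 matrices; the sample
#'   count is attached as attribute `n_samples`.
#' @export
read_beagle <- function(path, tol = 0.1) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1L) stop("empty BEAGLE file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1]]
  if (length(header) < 6L || (length(header) - 3L) %% 3L != 0L)
    stop("BEAGLE header must have 3 + 3*N columns", call. = FALSE)
  n_samples <- (length(header) - 3L) %/% 3L
  body <- fields[-1]
  body <- body[vapply(body, length, 1L) > 0L | nzchar(lines[-1])]
  rows <- vector("list", length(body))
  markers <- character(length(body))
  a1 <- character(length(body))
  a2 <- character(length(body))
  for (i in seq_along(body)) {
    f <- body[[i]]
    line_no <- i + 1L
    if (length(f) != length(header))
      stop("line ", line_no, ": expected ", length(header), " fields, got ",
           length(f), call. = FALSE)
    p <- suppressWarnings(as.numeric(f[-(1:3)]))
    if (anyNA(p))
      stop("line ", line_no, ": non-numeric genotype probability",
           call. = FALSE)
    m <- matrix(p, ncol = 3L, byrow = TRUE)
    s <- rowSums(m)
    bad <- which(abs(s - 1) > tol)
    if (length(bad))
      stop("line ", line_no, ": individual ", bad[1],
           " probabilities sum to ", signif(s[bad[1]], 4), call. = FALSE)
    rows[[i]] <- m / s
    markers[i] <- f[1]
    a1[i] <- f[2]
    a2[i] <- f[3]
  }
  out <- tibble::tibble(marker = markers, allele1 = a1, allele2 = a2,
                        probs = rows)
  attr(out, "n_samples") <- n_samples
  class(out) <- c("beagle_table", class(out))
  out
}

#' Write a BEAGLE genotype-probability file
#'
#' Inverse of [read_beagle()]. Also accepts a [genotype_likelihoods] or
#' [genotype_posterior] (written as one marker) via
#' [beagle_table_from_matrix()].
#'
#' @param x a `beagle_table`.
#' @param path output path; `.gz` compresses.
#' @param digits significant digits for probabilities.
#' @return `path`, invisibly.
#' @export
write_beagle <- function(x, path, digits = 6L) {
  stopifnot(inherits(x, "beagle_table"))
  n_samples <- attr(x, "n_samples")
  header <- c("marker", "allele1", "allele2",
              paste0("Ind", rep(seq_len(n_samples) - 1L, each = 3L)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(x))) {
    p <- signif(t(x$probs[[i]]), digits)
    writeLines(paste(c(x$marker[i], x$allele1[i], x$allele2[i],
                       format(as.vector(p), trim = TRUE, scientific = FALSE,
                              digits = digits)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_beagle
#' @param probs N x 3 probability (or scaled likelihood) matrix, or a
#'   [genotype_likelihoods]/[genotype_posterior] object.
#' @param marker,allele1,allele2 marker annotation.
#' @export
beagle_table_from_matrix <- function(probs, marker = "site_1", allele1 = "0",
                                     allele2 = "1") {
  if (inherits(probs, "genotype_likelihoods")) {
    m <- exp(probs$loglik)
    probs <- m / rowSums(m)
  } else if (inherits(probs, "genotype_posterior")) {
    probs <- probs$probs
  }
  probs <- as.matrix(probs)
  out <- tibble::tibble(marker = marker, allele1 = allele1,
                        allele2 = allele2, probs = list(unname(probs)))
  attr(out, "n_samples") <- nrow(probs)
  class(out) <- c("beagle_table", class(out))
  out
}

# genotype likelihoods for one marker of a beagle table (probabilities are
# used as scaled likelihoods; flat rows are depth-0 individuals)
beagle_likelihoods <- function(bt, i) {
  genotype_likelihoods(bt$probs[[i]], site_id = bt$marker[i])
}

#' Read a phenotype / covariate table
#'
#' Whitespace- or tab-separated table with a header; the first column is
#' the phenotype and any remaining numeric columns are covariates. Rows
#' must be in the same order as the individuals of the companion BEAGLE
#' file (the format carries no sample identifiers). `NA` marks missing
#' values; individuals with any missing value are flagged in the
#' completeness mask for listwise deletion.
#'
#' @param path file path.
#' @param n_expected optional expected number of individuals; a mismatch is
#'   an alignment error.
#' @return list with `phenotype` (numeric vector), `covariates` (numeric
#'   matrix or `NULL`), `complete` (logical mask), `binary` (phenotype
#'   detected as 0/1).
#' @export
read_pheno_cov <- function(path, n_expected = NULL) {
  df <- utils::read.table(path, header = TRUE)
  if (!ncol(df)) stop("phenotype file has no columns", call. = FALSE)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop("column '", names(df)[j], "' is not numeric", call. = FALSE)
  }
  if (!is.null(n_expected) && nrow(df) != n_expected)
    stop("phenotype file has ", nrow(df), " rows but genotype data has ",
         n_expected, " individuals", call. = FALSE)
  y <- df[[1]]
  Z <- if (ncol(df) > 1L) as.matrix(df[-1]) else NULL
  complete <- !is.na(y) & (if (is.null(Z)) TRUE else !rowSums(is.na(Z)))
  list(phenotype = y, covariates = Z, complete = complete,
       binary = all(y[!is.na(y)] %in% c(0, 1)))
}

#' Read admixture proportions or population allele frequencies
#'
#' `read_qmat()` reads an N x K admixture-proportion table (no header,
#' NGSadmix `.qopt` convention); rows are checked to sum to 1.
#' `read_pop_freqs()` reads an M x K table of per-marker population allele
#' frequencies (no header), M matching the marker count of the BEAGLE
#' file.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_qmat <- function(path) {
  Q <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(Q)) stop("Q matrix must be numeric", call. = FALSE)
  if (any(abs(rowSums(Q) - 1) > 1e-3))
    stop("Q rows must sum to 1", call. = FALSE)
  unname(Q / rowSums(Q))
}

#' @rdname read_qmat
#' @export
read_pop_freqs <- function(path) {
  F_pop <- as.matrix(utils::read.table(path, header = FALSE))
  if (!is.numeric(F_pop) || any(F_pop < 0) || any(F_pop > 1))
    stop("population frequencies must be numeric in [0, 1]", call. = FALSE)
  unname(F_pop)
}

#' Association scan over the markers of a BEAGLE table
#'
#' Runs one association method over every marker of a BEAGLE table against
#' a phenotype (and optional covariates), handling prior choice, allele
#' frequency estimation, minor-allele-frequency filtering and listwise
#' deletion of incomplete individuals. This is the data-frame-level driver
#' behind the `assoc` command-line tool.
#'
#' @param beagle a `beagle_table` from [read_beagle()].
#' @param pheno result of [read_pheno_cov()], or a numeric phenotype
#'   vector.
#' @param covariates optional covariate matrix (overrides the covariates in
#'   `pheno`).
#' @param model `"latent"`, `"dosage"`, `"score"` or `"hybrid"`.
#' @param family GLM family; `"auto"` picks binomial for a 0/1 phenotype
#'   and gaussian otherwise.
#' @param prior `"sample"` (Hardy-Weinberg at a sample allele frequency),
#'   `"individual"` (admixture-aware, needs `Q`), or `"none"` (use the file
#'   probabilities as posteriors directly).
#' @param Q admixture matrix for the individual prior.
#' @param pop_freqs per-marker population frequencies (M x K); estimated
#'   from the data given `Q` when omitted.
#' @param freqs optional per-marker sample allele frequencies; estimated
#'   from the data when omitted.
#' @param min_maf markers whose prior minor-allele frequency falls below
#'   this are skipped (default 0.005).
#' @param drop_zero_info exclude individuals with constant likelihood rows
#'   (zero reads) from the fit.
#' @param screen_alpha hybrid screen threshold.
#' @return tibble with one row per tested marker: `marker`, `allele1`,
#'   `allele2`, `freq`, `n`, `method`, `beta`, `se_beta`, `statistic`,
#'   `pvalue`, `iterations`, `converged`, `branch`.
#' @export
assoc_scan <- function(beagle, pheno, covariates = NULL, model = "latent",
                       family = "auto", prior = "sample", Q = NULL,
                       pop_freqs = NULL, freqs = NULL, min_maf = 0.005,
                       drop_zero_info = FALSE, screen_alpha = 0.05) {
  stopifnot(inherits(beagle, "beagle_table"))
  model <- match.arg(model, c("latent", "dosage", "score", "hybrid"))
  prior <- match.arg(prior, c("sample", "individual", "none"))
  if (is.numeric(pheno)) pheno <- list(phenotype = pheno, covariates = NULL,
                                       complete = !is.na(pheno),
                                       binary = all(pheno %in% c(0, 1)))
  n <- attr(beagle, "n_samples")
  if (length(pheno$phenotype) != n)
    stop("phenotype has ", length(pheno$phenotype),
         " individuals but BEAGLE file has ", n, call. = FALSE)
  Z <- covariates %||% pheno$covariates
  if (!is.null(Z)) Z <- as.matrix(Z)
  if (family == "auto") family <- if (pheno$binary) "binomial" else "gaussian"
  family <- check_family(family)
  if (prior == "individual") {
    if (is.null(Q)) stop("individual prior requires `Q`", call. = FALSE)
    if (nrow(Q) != n) stop("Q rows must match sample count", call. = FALSE)
  }
  keep0 <- pheno$complete
  if (!is.null(Z)) keep0 <- keep0 & !rowSums(is.na(Z))

  out <- lapply(seq_len(nrow(beagle)), function(i) {
    gl <- beagle_likelihoods(beagle, i)
    keep <- keep0
    if (drop_zero_info) keep <- keep & (is.na(gl$depth) | gl$depth != 0L)
    gl_i <- genotype_likelihoods(gl$loglik[keep, , drop = FALSE],
                                 depth = gl$depth[keep], log = TRUE,
                                 site_id = gl$site_id)
    y_i <- pheno$phenotype[keep]
    Z_i <- if (!is.null(Z)) Z[keep, , drop = FALSE]
    res <- marker_assoc(gl_i, y_i, Z_i, model, family, prior,
                        Q = if (!is.null(Q)) Q[keep, , drop = FALSE],
                        F_pop = if (!is.null(pop_freqs)) pop_freqs[i, ],
                        f = if (!is.null(freqs)) freqs[i],
                        min_maf = min_maf, screen_alpha = screen_alpha)
    if (is.null(res)) return(NULL)
    tibble::tibble(marker = beagle$marker[i], allele1 = beagle$allele1[i],
                   allele2 = beagle$allele2[i], freq = res$freq,
                   n = sum(keep), method = res$fit$method,
                   beta = res$beta, se_beta = res$fit$se_beta,
                   statistic = res$fit$statistic, pvalue = res$fit$pvalue,
                   iterations = res$fit$iterations,
                   converged = res$fit$converged, branch = res$fit$branch)
  })
  dplyr::bind_rows(out)
}

marker_assoc <- function(gl, y, Z, model, family, prior, Q = NULL,
                         F_pop = NULL, f = NULL, min_maf = 0.005,
                         screen_alpha = 0.05) {
  post_freq <- switch(prior,
    sample = {
      f_use <- f %||% tryCatch(estimate_sample_af(gl)$f,
                               error = function(e) NA_real_)
      if (is.na(f_use)) return(NULL)
      list(post = genotype_posterior(gl, prior_sample_af(f_use)),
           freq = f_use)
    },
    individual = {
      F_use <- F_pop %||% estimate_pop_freqs(gl, Q)$F
      pi_i <- individual_allele_frequency(Q, F_use)
      list(post = genotype_posterior(gl, prior_individual_af(pi_i)),
           freq = mean(pi_i))
    },
    none = {
      post <- genotype_posterior_from_probs(exp(gl$loglik) /
                                              rowSums(exp(gl$loglik)),
                                            depth = gl$depth)
      list(post = post, freq = mean(post$dosage) / 2)
    })
  if (min(post_freq$freq, 1 - post_freq$freq) < min_maf) return(NULL)
  fit <- switch(model,
    latent = fit_latent(y, post_freq$post, Z, family),
    dosage = fit_dosage(y, post_freq$post, Z, family),
    score = score_test(y, post_freq$post, Z, family),
    hybrid = fit_hybrid(y, post_freq$post, Z, family,
                        screen_alpha = screen_alpha))
  beta <- if (!is.null(fit$coefficients) &&
              "beta" %in% names(fit$coefficients))
    fit$coefficients[["beta"]] else NA_real_
  list(fit = fit, beta = beta, freq = post_freq$freq)
}

#' Flat key=value config files
#'
#' Serializes a [scenario_config()] or [case_control_config()] as a flat
#' `key=value` text file and reads it back.
#'
#' @param cfg a simulation config.
#' @param path file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: the config
#'   object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  type <- if (inherits(cfg, "case_control_config")) "case_control"
          else "scenario"
  keep <- !vapply(cfg, is.list, logical(1))
  kv <- vapply(cfg[keep], function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ","), character(1))
  kv <- kv[!is.na(cfg[keep]) | names(kv) == "scenario"]
  writeLines(c(paste0("type=", type),
               paste0(names(kv), "=", kv)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  vals <- stats::setNames(as.list(vals), keys)
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  if (identical(vals$type, "case_control")) {
    case_control_config(
      n_cases = num(vals$n_cases), n_controls = num(vals$n_controls),
      causal_freq = num(vals$causal_freq), prevalence = num(vals$prevalence),
      rr = num(vals$rr), depth_cases = num(vals$depth_cases),
      depth_controls = num(vals$depth_controls),
      drop_zero_depth = as.logical(vals$drop_zero_depth),
      error_rate = num(vals$error_rate))
  } else if (identical(vals$type, "scenario")) {
    scenario_config(
      n = num(vals$n), allele_freq = num(vals$allele_freq),
      structured = as.logical(vals$structured), beta = num(vals$beta),
      gamma = num(vals$gamma), delta = num(vals$delta),
      depth_levels = num(vals$depth_levels),
      error_rate = num(vals$error_rate), family = vals$family)
  } else stop("unknown config type in ", path, call. = FALSE)
}
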