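test_that("depth assignment realizes the requested phenotype correlation", {
  set.seed(51)
  y <- rnorm(4000)

  # delta = 0: independent coin flip in both phenotype halves
  d0 <- assign_depth(y, 0, c(1, 4))
  top <- rank(y, ties.method = "first") > 2000
  se <- 3 * sqrt(0.25 / 2000)
  expect_lt(abs(mean(d0[top] == 4) - 0.5), se)
  expect_lt(abs(mean(d0[!top] == 4) - 0.5), se)

  # delta = 1: deterministic split, cases all high depth
  status <- rbinom(4000, 1, 0.5)
  d1 <- assign_depth(status, 1, c(1, 4))
  expect_true(all(d1[status == 1] == 4))
  expect_true(all(d1[status == 0] == 1))

  # delta = 0.5: conditional probabilities (0.75, 0.25)
  d5 <- assign_depth(y, 0.5, c(1, 4))
  expect_lt(abs(mean(d5[top] == 4) - 0.75), 3 * sqrt(0.75 * 0.25 / 2000))
  expect_lt(abs(mean(d5[!top] == 4) - 0.25), 3 * sqrt(0.75 * 0.25 / 2000))

  expect_error(assign_depth(y, 1.2), "0, 1")
})

test_that("scenario cohorts follow the configured generative model", {
  # null scenario: phenotype standard normal, independent of genotype
  cfg0 <- scenario_config(n = 2000, allele_freq = 0.45, beta = 0, delta = 0)
  c0 <- simulate_cohort(cfg0, seed = 52)
  expect_gt(ks.test(c0$phenotype, "pnorm")$p.value, 0.01)
  expect_gt(cor.test(c0$phenotype, c0$genotypes)$p.value, 0.001)

  # genotype effect recovered by regression on the true genotypes
  cfg2 <- scenario_config("scenario2", n = 2000)
  c2 <- simulate_cohort(cfg2, seed = 53)
  ols <- summary(lm(c2$phenotype ~ c2$genotypes))$coefficients
  expect_lt(abs(ols[2, 1] - 0.3), 3 * ols[2, 2])

  # structured scenario: mean individual frequency is the mid-point of the
  # population frequencies under uniform admixture
  cfg4 <- scenario_config("scenario4", n = 2000)
  c4 <- simulate_cohort(cfg4, seed = 54)
  se_pi <- sd(c4$pi) / sqrt(2000)
  expect_lt(abs(mean(c4$pi) - 0.5), 3 * se_pi)
  expect_true(all(c4$pi >= 0.1 & c4$pi <= 0.9))
  # ancestry effect present: q explains phenotype variance
  expect_lt(summary(lm(c4$phenotype ~ c4$genotypes + c4$Q[, 1])
                    )$coefficients[3, 4], 1e-6)
})

test_that("case-control sampling matches the closed-form conditionals", {
  # rr = 1: cases and controls share the HWE genotype distribution
  d1 <- case_control_genotype_dist(1, 0.05, 0.10)
  expect_equal(d1$case, hwe_prior(0.05), tolerance = 1e-12)
  expect_equal(d1$control, hwe_prior(0.05), tolerance = 1e-12)

  # conditional distributions are proper and risk solves the prevalence
  d <- case_control_genotype_dist(1.1, 0.05, 0.10)
  expect_equal(sum(d$case), 1, tolerance = 1e-12)
  expect_equal(sum(d$control), 1, tolerance = 1e-12)
  expect_equal(sum(hwe_prior(0.05) * d$risk), 0.10, tolerance = 1e-12)

  # simulated case allele frequency matches the closed form
  cfg <- case_control_config(n_cases = 20000, n_controls = 2000,
                             rr = 1.1, depth_cases = 4, depth_controls = 4,
                             drop_zero_depth = FALSE)
  cohort <- simulate_cohort(cfg, seed = 55)
  g_case <- cohort$genotypes[cohort$phenotype == 1]
  af_expected <- sum(d$case * 0:2) / 2
  se <- sqrt(af_expected * (1 - af_expected) / (2 * 20000))
  expect_lt(abs(mean(g_case) / 2 - af_expected), 3 * se)

  expect_error(case_control_config(rr = 4, prevalence = 0.5),
               "risk exceeds 1")
})

test_that("zero-read removal drops the Poisson mass at zero", {
  cfg <- case_control_config(n_cases = 5000, n_controls = 20000,
                             depth_cases = 4, depth_controls = 1,
                             drop_zero_depth = TRUE)
  cohort <- simulate_cohort(cfg, seed = 56)
  n_controls_kept <- sum(cohort$phenotype == 0)
  kept_frac <- n_controls_kept / 20000
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 20000)
  expect_lt(abs((1 - kept_frac) - exp(-1)), 3 * se)
  expect_true(all(cohort$depth > 0))

  # without removal the zero-read individuals stay, with flat likelihoods
  cfg3 <- case_control_config(n_cases = 500, n_controls = 500,
                              drop_zero_depth = FALSE)
  c3 <- simulate_cohort(cfg3, seed = 56)
  expect_equal(length(c3$phenotype), 1000L)
  expect_gt(sum(c3$depth == 0), 0)
})

test_that("cohort simulation is reproducible bit-for-bit from its seed", {
  cfg <- scenario_config("scenario6", n = 300)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$gl$loglik, b$gl$loglik)
  expect_identical(a$Q, b$Q)

  res1 <- run_power_experiment(scenario_config("scenario2", n = 200), 5,
                               methods = c("true", "dosage"), seed = 17)
  res2 <- run_power_experiment(scenario_config("scenario2", n = 200), 5,
                               methods = c("true", "dosage"), seed = 17)
  expect_identical(as.data.frame(res1), as.data.frame(res2))
})

test_that("power experiments summarize methods, bias and info strata", {
  cfg <- case_control_config(n_cases = 1500, n_controls = 1500, rr = 1.5,
                             depth_cases = 4, depth_controls = 1)
  res <- run_power_experiment(cfg, 4, methods = c("true", "dosage",
                                                  "latent", "score",
                                                  "hybrid"),
                              alpha = 0.05, seed = 58, keep_details = TRUE)
  expect_s3_class(res, "power_result")
  expect_setequal(res$method, c("true", "dosage", "latent", "score",
                                "hybrid"))
  expect_true(all(res$power >= 0 & res$power <= 1))
  # info measure ordered by depth: cases (4X) better predicted than
  # controls (1X) in every replicate
  det <- attr(res, "details")
  d1 <- det[det$method == "dosage", ]
  expect_true(all(d1$r2_high > d1$r2_low))
  # score rows carry no effect estimate
  expect_true(all(is.na(res$mean_beta[res$method == "score"])))
  # plot method returns a ggplot without error
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("configs round-trip through flat key=value files", {
  path <- tempfile(fileext = ".conf")
  cfg <- case_control_config(preset = "table2", rr = 1.12)
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$rr, 1.12)
  expect_equal(cfg2$causal_freq, 0.05)
  expect_equal(cfg2$prevalence, 0.10)
  expect_true(cfg2$drop_zero_depth)
  expect_equal(cfg2$genotype_dist, cfg$genotype_dist)

  cfgs <- scenario_config("scenario3", n = 500)
  write_config(cfgs, path)
  cfgs2 <- read_config(path)
  expect_equal(cfgs2$allele_freq, c(0.9, 0.1))
  expect_true(cfgs2$structured)
  expect_equal(cfgs2$gamma, 1)
  expect_equal(cfgs2$delta, 0.5)
})
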