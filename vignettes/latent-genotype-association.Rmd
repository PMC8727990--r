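---
title: "Association testing with genotype uncertainty: the latent-genotype GLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association testing with genotype uncertainty: the latent-genotype GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentgwas)
```

## The problem

In low-depth sequencing studies (and, analogously, in imputation-based
studies) the genotype $G_i \in \{0, 1, 2\}$ of individual $i$ at a biallelic
site is not observed. What the sequencer delivers is a handful of reads
$x_i$, summarized by the *genotype likelihood* $p(x_i \mid G_i = g)$.
Calling a best-guess genotype and regressing on it discards the
uncertainty; at 1X coverage it is also badly inaccurate. `latentgwas`
implements the alternative: carry the full genotype distribution through
the association model.

Three ingredients are involved:

1. **Genotype posteriors.** With an allele-frequency prior under
   Hardy–Weinberg equilibrium,
   $p(g \mid f) = \big((1-f)^2,\ 2f(1-f),\ f^2\big)$, Bayes' rule gives
   $p(G_i = g \mid x_i) \propto p(x_i \mid g)\, p(g \mid f)$. In a
   structured sample a single sample-wide $f$ misdescribes everyone; the
   *individual allele frequency* $\pi_i = \sum_k q_{ik} F_k$ — admixture
   proportions $q_{ik}$ weighting population frequencies $F_k$ — replaces
   it ([`prior_individual_af()`]).
2. **The latent-genotype GLM.** The phenotype model is a generalized
   linear model with linear predictor
   $\eta_{ig} = \alpha + \beta g + z_i^\top \gamma$ (identity, logit or
   log link). The genotype is marginalized:
   $$\ell(\theta) = \sum_{i=1}^N \log \sum_{g \in \{0,1,2\}}
     p(y_i \mid G_i = g, z_i, \theta)\, p(G_i = g \mid x_i).$$
   `fit_latent()` maximizes this by EM; `fit_dosage()` is the conventional
   alternative that regresses on the posterior mean $E[G_i \mid x_i]$;
   `score_test()` tests $\beta = 0$ without fitting the alternative;
   `fit_hybrid()` screens with the score test and refits significant sites
   with the EM.
3. **A simulation engine** reproducing the power/false-positive-rate/bias
   experiments that motivate the method: quantitative-trait scenarios with
   and without population structure and with sequencing depth correlated
   with the phenotype, and a large case-control design in which cases and
   controls are sequenced at different depths.

## The EM algorithm

The E-step computes genotype responsibilities
$w_{ig} \propto p(G_i = g \mid x_i)\, p(y_i \mid G_i = g, z_i, \theta)$.
The M-step solves a weighted GLM on the $3N$-row expanded design in which
each individual appears once per candidate genotype with weight $w_{ig}$:
weighted least squares for the gaussian family, with
$\sigma^2 \leftarrow \sum_{ig} w_{ig}(y_i - \eta_{ig})^2 / N$, and weighted
IRLS for binomial and poisson. The inner IRLS is run to convergence
(tolerance $10^{-8}$) rather than taking a single generalized-EM step, so
each M-step fully maximizes the expected complete-data log-likelihood and
the observed-data log-likelihood is non-decreasing at every iteration —
the test suite asserts this trace monotonicity on every fit it inspects.

The EM stops when the log-likelihood changes by less than `tol`
($10^{-6}$ by default) or after `max_iter` (100) iterations;
non-convergence is reported in the `converged` flag rather than raised, so
a genome scan does not abort on one badly behaved site. Starting values
come from the dosage regression ("priming"): its coefficients are already
close to the latent optimum, which cuts the iteration count substantially
without changing the converged fit (both properties are under test).

Two degeneracies are handled explicitly. An individual with zero reads has
a constant likelihood row and simply receives the prior. A site whose
posterior dosages have variance below $10^{-8}$ carries no information
about $\beta$ at all; such sites are flagged `estimable = FALSE` and not
tested, which avoids reporting spuriously enormous standard errors.

## Standard errors and tests

Standard errors are square roots of the diagonal of the inverse *observed*
Fisher information of the marginal log-likelihood at $\hat\theta$,
computed by central finite differences of the analytic score with step
$10^{-5}\max(1, |\theta_j|)$; for the gaussian family $\sigma^2$ is a
parameter of the information matrix. With certain genotypes this reduces
exactly to the classical GLM covariance (with the maximum-likelihood
residual variance), which the tests verify, along with agreement to an
independent dense numerical Hessian and calibration of the reported SE
against the empirical spread of $\hat\beta$ over replicate simulations.

The default p-value on $\beta$ is a Wald test against $\chi^2_1$; a
likelihood-ratio test is available (`test = "lrt"`), exploiting that the
null model collapses to an ordinary GLM because the genotype term drops
out of the mixture at $\beta = 0$.

The score test evaluates the score of the marginal likelihood in $\beta$
at the null MLE. At $\beta = 0$ the responsibilities equal the posterior
probabilities, so both the score, $U = \sum_i \dot\ell_i\, E[G_i \mid
x_i]$, and the observed information have closed forms in the posterior
moments $E[G_i]$ and $E[G_i^2]$. The efficient information profiles out
the intercept and covariate effects; the gaussian residual variance is
plugged in at its null MLE rather than profiled, a deliberate choice that
makes the certain-genotype case agree exactly with the textbook Rao
statistic (and with `anova(..., test = "Rao")`), which would not hold if
$\sigma^2$ were carried through the observed-information profiling. The
hybrid method applies the score test everywhere and runs the EM only for
sites with score p-value below `screen_alpha` (default 0.05, the
threshold being configurable because no canonical value exists); for any
stricter downstream threshold the hybrid and full-EM significance calls
coincide.

Covariates are estimated jointly inside the EM, never residualized out of
the phenotype beforehand: residualizing first biases $\hat\beta$ whenever
a covariate correlates with the tested genotype, which is precisely the
conditional-analysis setting where joint estimation matters.

## Allele-frequency machinery

`estimate_sample_af()` is the EM $f \leftarrow \frac{1}{2N}\sum_i E[G_i
\mid x_i, f]$, initialized at $f_0 = 0.25$ (the likelihood in $f$ is
well-behaved and unimodal in practice; the starting value is fixed for
reproducibility), converging when $|\Delta f| < 10^{-8}$. With certain
genotypes it reduces to allele counting, and the tests also check the
maximizer against a dense grid search of the marginal likelihood.

`estimate_pop_freqs()` estimates per-population frequencies with the
admixture proportions held fixed and known. The M-step attributes each
individual's expected minor-allele count to population $k$ in proportion
to $q_{ik}F_k / \pi_i$ (and major counts via $q_{ik}(1-F_k)/(1-\pi_i)$).
Frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ during iteration so the
Hardy–Weinberg prior never degenerates mid-run; if the likelihood is
maximized on the boundary the reported value is unclamped to 0 or 1. A
population with essentially zero total admixture weight is not
identifiable; it is reported at 0.5 with a warning and
`converged = FALSE`.

## The simulation engine and what it does (and does not) emulate

`simulate_genotype_likelihoods()` uses the standard biallelic read model:
individual $i$ receives $d_i \sim \text{Poisson}(\lambda_i)$ reads, each
reporting the minor allele with probability $g/2\,(1-\epsilon) + (1 -
g/2)\,\epsilon$, with per-read error $\epsilon = 0.01$ by default.
Likelihoods are stored and combined in log space with max-normalization,
so deep coverage cannot underflow.

The quantitative-trait scenarios (`scenario_config()`, presets
`scenario1`–`scenario6`) simulate $N = 1000$ individuals with phenotype
$y_i \sim \mathcal N(\beta g_i + \gamma q_i,\ 1)$. Structure draws
$q_i \sim U(0,1)$ over two populations at frequencies $(0.9, 0.1)$, with
$g_i \sim \text{Binomial}(2, \pi_i)$; $\gamma = 1$ so ancestry is a strong
confounder, and $\beta = 0.3$ where a genotype effect is present —
realistic effect sizes for a well-powered quantitative-trait study at
this sample size. Sequencing depth is a two-level design, mean 1X or 4X
(`depth_levels = c(1, 4)`, chosen to mirror the case-control depth
contrast); `assign_depth()` implements the depth–phenotype correlation
$\delta$: individuals in the top phenotype half (or cases) are placed in
the high-depth group with probability $0.5 + \delta/2$. This rank-based
two-group mechanism realizes, with a single interpretable parameter, the
qualitative coupling "large phenotype $\Rightarrow$ probably high depth";
$\delta = 0$ decouples them and $\delta = 1$ splits deterministically.

The case-control design (`case_control_config()`, presets `table2` /
`table3`) gives genotype $g$ a multiplicative per-allele disease risk
$k\,\mathrm{RR}^g$ with the baseline $k$ solved so that the population
prevalence matches under Hardy–Weinberg proportions; case and control
genotypes are sampled from the exact conditional distributions
(`case_control_genotype_dist()`). Defaults are 50,000 cases at 4X and
50,000 controls at 1X, causal frequency 0.05, prevalence 0.10; `table2`
removes zero-read individuals and `table3` keeps them.
`run_power_experiment()` replicates a design, runs any subset of methods
(true-genotype GLM, dosage, latent under any prior choice, score, hybrid)
on *shared* per-replicate data with deterministically derived sub-seeds,
and reports power, mean effect and bias, SE calibration and
depth-stratified MACH-style info measures ($R^2 =
\mathrm{Var}(\text{dosage})/2f(1-f)$, with the $N-1$ variance).

What passing simulations show — and what they do not. The engine
reproduces everything the main design fixes: the true-genotype logistic
powers of the case-control grid, the null calibration of all tests at
stringent thresholds, the superior per-replicate p-values of the latent
model over dosage regression under differential depth, the downward bias
of the sample-frequency prior and its repair by the individual-frequency
prior under structure, and the power advantage of the individual prior.
Two features of the original study depend on finer read-simulator detail
than is published: the absolute dosage/latent power levels at
intermediate relative risks, and the absolute info-measure values (a
plain per-read error model cannot exceed $R^2 \approx 0.5$ at 1X mean
depth, whatever the error rate, because the per-depth information is
concave in depth). Our read model is also *not* a model of real
sequencing artifacts — no mapping error, no base-quality variation, no
allelic balance bias — so passing tests certify the statistical machinery
under the stated generative model, not performance on any particular real
data set. Likewise the latent model assumes the prior used for the
posterior is the marginal truth; in outcome-dependently sampled
case-control data that assumption is mildly violated for both dosage and
latent methods, and with highly informative reads this produces a small
upward tilt of the latent estimate where under noisy reads dosage
attenuation dominates instead.

## Numerical choices

* Likelihoods in log space everywhere; posterior normalization by row-max
  subtraction; `logSumExp` for the marginal likelihood.
* EM: $|\Delta\ell| < 10^{-6}$, cap 100 iterations, report rather than
  raise non-convergence. Inner IRLS tolerance $10^{-8}$, with
  step-halving engaged only on large steps.
* M-step linear algebra by Cholesky-solved normal equations on the
  expanded design (2–5 columns); a failed or near-singular factorization
  raises a singular-fit error.
* Minor-allele coding is taken from the input file and never re-polarized
  by frequency, so the sign of $\beta$ is deterministic.
* Zero-read individuals are kept by default; exclusion
  (`drop_zero_info`, `drop_zero_depth`) is a caller decision.
* BEAGLE triplets that sum to $1 \pm 0.1$ are renormalized; anything
  worse is a parse error with a line number.

## Problem sizes used by the packaged experiments

The published experiments use 10,000 replicates per point; the packaged
test suite and the acceptance script rerun them at desk scale — 200–2000
replicates per point, chosen so each check retains 3-standard-error
resolution around its target while the whole suite stays in the tens of
minutes on one core. The null-calibration check of the case-control
design runs at a quarter-scale cohort (12,500 + 12,500), the package's
choice on the grounds that a test's false-positive rate, unlike its
power, does not depend on cohort size. Per-replicate seeds are derived
from one master seed, so every experiment is reproducible bit for bit.

## Known limitations

* Biallelic sites only; no genotype calling; no per-base quality-aware
  likelihood model (likelihoods are accepted from file, so an external
  caller can supply richer models).
* Admixture proportions are taken as known when forming the individual
  prior; estimating $Q$ itself is out of scope.
* No relatedness/mixed-model correction and no multi-site joint models.
* The hybrid's score screen is anti-conservative only in the trivial
  sense that effect sizes are reported solely for screened-in sites;
  p-values are unaffected at thresholds below the screen.
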