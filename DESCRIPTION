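Package: latentgwas
Title: Latent-Genotype Association Testing for Low-Depth Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association testing for genetic studies where the genotype is
    observed with uncertainty, as in low-depth sequencing or imputation.
    Computes genotype posteriors from genotype likelihoods under sample- or
    individual-allele-frequency (admixture-aware) priors, estimates allele
    frequencies by EM, and fits a generalized linear model in which the
    unobserved genotype enters as a latent variable, maximized by EM with
    observed-Fisher-information standard errors. Dosage regression, a score
    test and a score-screened hybrid are provided alongside, together with a
    simulation engine for power, false-positive-rate and effect-size-bias
    experiments under sequencing-depth/phenotype correlation and population
    structure, BEAGLE-format input and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    generics,
    ggplot2,
    optparse
Suggests:
    tidyr,
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
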