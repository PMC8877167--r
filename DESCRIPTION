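Package: mkshift
Title: McDonald-Kreitman Estimates of Adaptive Evolution under Population-Size Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how changes in effective population size bias
    McDonald-Kreitman style estimates of the rate of adaptive protein
    evolution. Provides closed-form predictions of the bias in omega_a and
    alpha under a two-epoch population history with a gamma distribution of
    deleterious fitness effects; a GammaZero maximum-likelihood estimator
    that fits the gamma DFE to paired selected/neutral site frequency
    spectra by Poisson likelihood and derives omega, omega_na, omega_a and
    alpha; site-level analysis pipelines for amino-acid pairs separated by
    a single mutational step (with four-fold degenerate synonymous
    comparators matched by mutational type), relative solvent accessibility
    bins, and GC-biased gene conversion filtering; variance-weighted
    regression and randomization machinery; and a synthetic-data generator
    with known truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
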