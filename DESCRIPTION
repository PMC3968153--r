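Package: rvlrt
Title: Likelihood-Ratio Tests for Rare-Variant Set Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene- or set-based association tests between rare genetic
    variants and a continuous phenotype. Implements the likelihood-ratio
    test (LRT) and restricted likelihood-ratio test (ReLRT) of a zero
    variance component in a weighted mixed-effects model, together with
    the equivalent kernel-machine formulation, using exact finite-sample
    null distributions simulated from the tests' eigenvalue
    representation. Score-test comparators (burden, SKAT, SKAT-O) with
    mixture-of-chi-square p-values, Beta(1,25) minor-allele-frequency
    weights, a self-contained rare-variant data simulator, and a
    type-I-error / power study harness are included. Results are returned
    as tibbles with broom-style tidy() and glance() methods and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
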