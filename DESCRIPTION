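Package: purebeta
Title: Purity-Aware Correction of Tumor DNA Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free correction of Illumina 450K/EPIC DNA methylation
    beta values for tumor purity. Each CpG is modelled as a finite mixture of
    up to three linear regressions of beta on (1 - purity), fitted by
    expectation-maximization with BIC model selection, so that latent sample
    populations sharing a pure-tumor methylation state are discovered without
    reference normal samples. Population-wise linear detrending then yields a
    purified-tumor beta matrix (extrapolation to 100% tumor content) and an
    inferred normal-background beta matrix (extrapolation to 0% tumor
    content). Includes a synthetic cohort generator with the same
    two-compartment mixing structure, purity-perturbation robustness
    utilities, clustering-based evaluation metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    parallel,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
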