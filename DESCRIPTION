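Package: formateswitch
Title: Kinetic Modelling and Omics Statistics for the Formate-Dependent Metabolic Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state kinetic modelling of the coupling between formate
    production, de novo purine synthesis and adenine-nucleotide energy
    metabolism, including the low-to-high adenine nucleotide switch and the
    formate overflow threshold. Provides detailed multi-step rate models of
    glycolysis and oxidative phosphorylation with effective Michaelis-Menten
    fitting, an ATP-threshold flux-balance model of orotate and
    argininosuccinate accumulation, permutation-based association statistics
    for proteomics and metabolomics tables scored against a one-carbon
    availability index, gene-set enrichment of slopes, synthetic data
    generators emulating the study designs, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
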