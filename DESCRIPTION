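Package: auxintor
Title: Chemogenomic and Kinetic Analysis of Auxin-Mediated TORC1 Inhibition in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse how indole-3-acetic acid (IAA, auxin) limits
    growth through TORC1 in budding yeast: fitness scoring of saturated
    transposon (SATAY) insertion libraries, z-score calling and set-overlap
    statistics for colony-size chemical-genetic screens, steady-state
    enzyme-kinetic fits that discriminate the inhibition mechanism and
    estimate Km and Ki, four-parameter logistic dose-response (IC50)
    fitting, Cheng-Prusoff effective-IC50 physiology predictions, and
    isotope-dilution LC-MS quantification. Every pipeline input can be
    simulated with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
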