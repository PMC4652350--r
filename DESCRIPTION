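Package: riceprot
Title: Label-Free Spectral-Count Proteomics of Cold-Stressed Rice Germination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for label-free differential proteomics by
    spectral counting, built around the comparison of cold-germination
    resistant and susceptible rice varieties. Implements normalized spectral
    abundance factor (NSAF) quantification with replicate filtering and
    pseudocount handling, ln-scale two-sample t-tests with fold-change
    classification, cross-variety response categorization, protein isoelectric
    point and molecular weight profiling (EMBOSS-compatible), hypergeometric
    GO term enrichment with FDR control, and a calibrated synthetic
    spectral-count generator with detection dropout for end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
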