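Package: aipforest
Title: Anti-Inflammatory Peptide Identification from Sequence Composition
    Features with Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies anti-inflammatory peptides (AIPs) from amino-acid
    sequences. Encodes peptides with amino acid composition (AAC), dipeptide
    deviation from expected mean (DDE) and g-gap dipeptide composition (GDC)
    descriptors, ranks features by the ANOVA F score, selects an optimal
    subset by incremental feature selection under cross-validated AUC, and
    fits a random-forest classifier. Ships a synthetic peptide generator with
    controllable compositional and dipeptide-transition class signal so the
    whole pipeline is testable without external data, plus evaluation tools
    (sensitivity, specificity, accuracy, Matthews correlation, ROC/AUC) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
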