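Package: sgamist
Title: Genetic Interaction Scoring and Dose-Response Analysis for
    Mistranslating tRNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the fitness consequences of mistranslating
    tRNA variants in Saccharomyces cerevisiae. Implements colony-array
    normalization and multiplicative-model interaction scoring (epsilon =
    W_AB - W_A * W_B) for synthetic genetic array (SGA) screens against
    temperature-sensitive allele collections, spot-assay validation of double
    mutants against the multiplicative expectation, logistic growth-curve
    fitting with doubling-time estimation, proline-to-serine mistranslation
    frequency estimation from peptide-spectrum-match tables with the sibling
    peptide qualification rule, and classification of dose-response profiles
    across regulated mistranslation levels. A synthetic-data module generates
    every input kind with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
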