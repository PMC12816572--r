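Package: uorfkit
Title: Upstream Open Reading Frame Analysis of 5'UTR Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of AUG-initiated upstream open reading frames (uORFs)
    in 5' untranslated regions, structural classification of 5'UTR variant
    consequences (uAUG creation, uORF stop loss, overlapping-ORF read-through,
    frameshift, Kozak-context change), allele-frequency credibility filtering
    for rare-disease variant prioritisation, and dual-reporter (Gaussia
    luciferase / secreted alkaline phosphatase) assay statistics with one-way
    ANOVA and Tukey HSD comparisons. Includes a constraint-driven synthetic
    fixture emulating the PKD1 5'UTR so the whole pathway runs end to end
    without external data.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
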