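Package: histact
Title: Gene Activity Prediction from Binarized Histone Modification Patterns
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts binary gene transcription activity (active/inactive)
    from the presence or absence of histone modifications at 24
    nucleosome-sized gene regions flanking the transcription start and
    termination sites. Implements expression-ranked occurrence-frequency
    profiles, best-first CART-style decision-tree induction with an exact
    nested k-node prune path, a cumulative-sum change-point procedure that
    derives a non-arbitrary activity threshold from tree-based +1/-1 gene
    designations, exhaustive multifactor dimensionality reduction (MDR)
    with cross-validated balanced accuracy, and a synthetic-data generator
    emulating CD4+ T-cell ChIP-seq and expression inputs with planted,
    recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
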