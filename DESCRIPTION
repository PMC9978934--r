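Package: indigoferm
Title: Microbiota Succession and Dyeing-Phenotype Analytics for Indigo Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing bacterial community succession during alkaline
    indigo (sukumo) fermentation and linking it to dyeing capacity. Provides
    CIELAB colorimetric scoring of dyed-cloth swatches, relative-abundance and
    rare-taxon ("Others") summaries, rarefaction-based alpha diversity,
    redundancy analysis against environmental drivers (pH, redox potential,
    decaying wheat-bran pulses), Spearman co-occurrence networks, predicted
    metagenome construction from taxon-by-gene copy tables with subpathway
    ratio screens, and a gene-to-phenotype correlation screen with taxon
    contribution decomposition. A seeded synthetic fermentation generator with
    planted causal gene families supports end-to-end validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    png,
    jsonlite,
    withr
Config/testthat/edition: 3
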