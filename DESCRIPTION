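Package: tomoevo
Title: Comparative Spatial Transcriptomics of Nematode RNA Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of RNA tomography (tomo-seq) data along the nematode
    anterior-posterior axis: section-total normalization and per-gene z-score
    profiles, marker-peak segmentation of cryosections into anatomical regions,
    pooled regional expression profiles with expressed/regional gene calling,
    reciprocal-best-hit one-to-one orthology, cross-species region overlap and
    protein-domain overrepresentation via exact tests with FDR control,
    spatially resolved phylostratigraphy over a ladder phylogeny, dN/dS
    summaries by gene age and region, representative-isoform selection with
    longest-ORF extraction, and a fully parameterised synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    withr,
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
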