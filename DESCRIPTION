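Package: svpeaks
Title: Detection of Recurrent Structural Variant Hotspots and Their
    Expression Consequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic hotspot regions recurrently targeted by
    structural variants (SVs) across a cancer cohort using a sliding-window
    peak-calling and peak-merging approach, annotates hotspots with nearby
    genes and overlapping regulatory elements, evaluates the association of
    hotspot SVs (overall, per SV type, and stratified by copy-number status)
    with the expression of nearby genes via a twelve-comparison battery
    combined with Fisher's method and Benjamini-Hochberg false discovery
    rate control, groups dependent peaks into families, and emits ranked
    reports, genome-browser tracks, and region/expression figures. Includes
    a fully deterministic synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    IRanges,
    jsonlite,
    patchwork,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
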