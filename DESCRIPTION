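Package: celltracks
Title: Import, Analyse and Render Cell-Tracking Trajectories and Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the output of automatic cell trackers:
    readers and writers for bounding-box trajectory tables with lineage
    (parent) links and for per-time-step statistic tables, an importer for
    the Cell Tracking Challenge result format (track text file plus labelled
    mask images), assembly of observations into tracks and a lineage forest
    with clonal-family queries, per-step direction vectors and displacement
    histograms, recursive rectangular partitioning of the imaging field for
    per-region motion statistics, viewport (zoom/pan/minimap) coordinate
    maths, deterministic SVG renderers for the coordinated trajectory,
    lineage and statistic views plus animation frame export, and a seeded
    synthetic-data generator (biased random walks with division, appearance
    and disappearance, including a durotaxis scenario) that emits every
    supported input format together with a ground-truth event log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    tiff,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
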