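Package: pathstain
Title: Omics Data Overlays and Voronoi Map Staining on Positioned Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Visualizes multi-omics data on top of positioned biological
    network maps. Provides a self-contained JSON map descriptor with HUGO
    gene-symbol indexing and zoom-level visibility, typed ingestion of
    tab-delimited omics matrices with type-appropriate sample-group
    summarization, marker, heatmap, barplot and glyph overlays, the Voronoi
    "map staining" background representation with extent-limited territories,
    slippy-map 256-pixel tile pyramids with semantic zoom, hypergeometric
    enrichment of gene lists against map modules, and a session-based JSON
    command engine with a batch command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
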