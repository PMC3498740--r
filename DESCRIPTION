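Package: atlaspaint
Title: Expression-Atlas Painting of Anatomical Images and Network Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Color-codes segments of 2D anatomical images from normalized
    expression values using a labelfield/legend scheme: a source image is
    paired with a pixel-aligned labelfield in which every region of interest
    is flat-filled with a unique color, and a legend maps label colors to
    the spatial identifiers used in a long-format expression template.
    Produces one painted image per gene and condition under a shared
    value-to-color scale (including stage montages and condition-difference
    views), embeds the painted images into the nodes of biological networks
    (GML, SIF, edge-list CSV, SBML topology) by gene-identifier matching,
    and exports static deliverables: per-gene PNGs, visual-clustering
    grids, stacked comparisons, deterministic SVG network renders, and a
    self-contained HTML gallery. A deterministic synthetic-data generator
    builds complete labelfield/legend/template/network bundles for testing
    and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    xml2,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    readxl,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
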