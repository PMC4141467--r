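Package: edgelight
Title: Cortical Edge-Integration Modelling of Surface Lightness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a cortical edge-integration account of achromatic
    surface lightness. Generates classical psychophysical displays
    (disk-annulus, simultaneous contrast, staircase-Gelb paper series with
    optional insulating frame, Craik-O'Brien-Cornsweet edges, gradient
    backgrounds), extracts directed steps in log luminance at region borders,
    selects integration paths from a common background via a region adjacency
    graph with attentional-spotlight and edge-interpretation gain control, and
    integrates polarity- and distance-weighted edge signals into separate
    lightness and darkness channel maps, per-region lightness estimates, and
    anchored reflectance estimates. Includes end-to-end experiments
    reproducing power-law compression of the Gelb lightness scale, insulation,
    ideal-observer matching slopes, contour-masking and annulus-width effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
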