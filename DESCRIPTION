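Package: ciliaflow
Title: Quantification of Cilia-Driven Bead Transport from Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mucociliary transport from time-lapse
    movies of tracer beads on ciliated epithelia. Implements a particle
    image velocimetry (PIV) pipeline that maps per-window flow velocity
    fields, classifies active regions against a noise floor, and reports
    the fraction of a circular culture moving above a control-derived
    speed threshold; a coordination pipeline that segments moving area
    from temporal intensity variability and scores local alignment of
    flow directions with circular statistics; and a bead tracking and
    whole-specimen drift module for embryo surface-flow assays. A
    synthetic bead-movie simulator with full ground truth (active-area
    masks, direction fields, tracks, drift) supports validation of every
    metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: ImageAnalysis, CellBiology, Visualization
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
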