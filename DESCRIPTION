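Package: seedscape
Title: Multi-Scale Landscape Analysis of Tree-Seedling Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how landscape composition and configuration
    shape the alpha-, beta- and gamma-diversity of plot-sampled plant
    communities across spatial scales. Implements the Hill-number
    (effective-number-of-species) decomposition of patch-level communities,
    Chao-Shen sample coverage, six class-level landscape metrics (forest and
    secondary-forest cover, patch density, aggregation index, patch isolation,
    edge contrast) inside nested circular buffers, leave-two-out
    cross-validated scale-of-effect selection with bootstrap uncertainty, and
    AICc-based multimodel inference with model averaging. A neutral-landscape
    and community simulator with a planted scale of effect makes the whole
    pipeline testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
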