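Package: polfrap
Title: Kinetic Inference for RNA Polymerase II Strip-FRAP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for strip-FRAP (fluorescence recovery after
    photobleaching) measurements of GFP-tagged RNA polymerase II. Provides
    preprocessing of raw per-cell intensity traces (background correction,
    pre-bleach normalization, condition averaging), a particle-based Monte
    Carlo simulator of nuclear diffusion with two immobile chromatin-bound
    states (promoter-bound and elongating), a grid-search fitting engine that
    extracts fraction sizes and chromatin residence times from recovery
    curves, and a synthetic-data generator emulating unperturbed and
    UV-damaged transcription-kinetic regimes for end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
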