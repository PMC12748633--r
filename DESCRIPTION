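Package: phasedig
Title: Digitize Binary Phase Diagrams into Probabilistic Phase-State Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Semi-automatic digitization of raster images of binary
    (surfactant-water) temperature-composition phase diagrams. Provides an
    image pipeline (binarization, plot-frame detection, projective
    rectification, component filtering, topology-preserving thinning and
    region labeling), guide-point curve tracing over the pixel graph, a
    distance-kernel sampler that converts labeled diagrams into gridded
    probabilistic phase-state tables, readers, writers and validators for the
    PhDat JSON record dialect, a controlled vocabulary of lyotropic
    phase-state labels, dataset-level frequency summaries, and a synthetic
    diagram generator with an exact vector-geometry oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
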