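Package: toothcrack
Title: Microcrack Network Analysis in Micro-CT Tooth Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional analysis of microcrack networks in
    X-ray micro-computed tomography scans of teeth. Provides synthetic tooth
    phantoms with ground-truth labels (enamel shell, dentin core, pulp cavity,
    planar crack networks, noise and scan artifacts), tile-based per-slice
    voxel classification into crack/enamel/dentin/air with a pluggable backend
    (a small trainable convolutional network and a deterministic thresholding
    oracle are included), three-axis consensus voting for crack voxels,
    crack-mask fill-in to reconstruct the crack-free tooth, connected-component
    isolation of crack networks, crack morphometry (volume fraction, local
    width by distance-transform thickness, structure-tensor plane orientations,
    distance-to-crack and projected-density maps), slab/sector partitioning of
    the tooth, and closed-form fracture-mechanics estimates relating crack
    geometry, material constants and applied stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
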