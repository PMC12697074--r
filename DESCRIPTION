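Package: VoronoiCapsule
Title: Voronoi Tessellation Verification and Nanoscale Morphometry for
    Honeycomb-Like Bacterial Capsule Micrographs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Geometric and image-based analysis of honeycomb-like capsule
    surfaces and sponge-like biofilms as seen in electron micrographs of
    Micrococcus. Constructs Voronoi diagrams and Delaunay triangulations from
    pore-center seed points by half-plane intersection, verifies the
    perpendicularity of Voronoi edges against their dual Delaunay edges,
    and scores congruence between manually traced wall networks and the
    computed ideal tessellation. A binarization pipeline (edge emphasis,
    Gaussian smoothing, Otsu thresholding) yields cell/cavity area fractions
    and nanoscale morphometry (pore diameter and depth, layer thickness,
    cell major axis). A synthetic-micrograph generator with ground-truth
    masks makes every stage testable without microscope data, and a small
    statistics module provides the summary statistics, pooled-variance
    t-test, infrared band-area ratios and the diffusion barrier time used
    alongside the imaging results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, BiomedicalInformatics, CellBiology, Visualization
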