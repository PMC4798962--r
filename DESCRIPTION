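Package: vesselpol
Title: Endothelial Polarity Versus Blood Flow in Vascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying endothelial nucleus-to-Golgi axial
    polarity relative to simulated blood flow in planar vascular networks.
    Reconstructs a measured vessel graph from a binary lumen mask
    (skeletonization, maximum-inscribed-circle radii, junction topology),
    solves steady Poiseuille/Kirchhoff network flow to obtain per-segment wall
    shear stress (WSS) and flow direction, joins per-cell polarity vectors to
    local flow, and applies circular statistics: mean-direction confidence
    arcs, Rayleigh and two-sample Kuiper tests, WSS-binned anti-alignment
    fractions with a threshold-crossing shear readout, and scalar-product
    regression gradients. Includes a synthetic retinal-style plexus generator
    with a shear-threshold polarization response so every stage can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
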