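Package: atheroFEM
Title: Finite-Element Simulation of Inflammation-Driven Atherosclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled three-field continuum model of atherosclerotic plaque
    growth in an artery wall: quasi-static finite-strain mechanics with a
    Holzapfel-Gasser-Ogden anisotropic hyperelastic wall and multiplicative
    inflammation-driven volumetric growth, steady diffusion-reaction nutrient
    transport nourished by a stochastic fractal vasa-vasorum network, and an
    Allen-Cahn phase field for the inflamed region advected toward nutrient
    scarcity. Structured quadrilateral/hexahedral meshes of 2D annulus and 3D
    tube artery geometries, a monolithic Newton-Raphson multi-field solver
    with backward-Euler pseudo-time stepping, and post-processing of stenosis
    degree, lumen area and principal wall stresses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
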