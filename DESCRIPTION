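Package: keratofem
Title: Multizone Corneal Finite-Element Biomechanics and Stress-Free
    Geometry Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Patient-style corneal biomechanics at desk scale: a multizone
    anisotropic hyperelastic finite-element model of the cornea (two-family
    Holzapfel collagen reinforcement over a Mooney-Rivlin matrix, quasi-
    incompressible, zone-wise fiber parameters, follower intraocular-pressure
    loading, embedded or pivoting limbus constraints), together with two
    inverse iterative methods -- the displacements method and the prestress
    method -- that recover the stress-free corneal geometry and the
    physiological stress and strain fields from a pressurized (measured)
    geometry.  Includes a synthetic cornea generator emulating keratoconic
    topographies, a structured zone-conforming hexahedral mesher, field
    post-processing (von Mises stress, equivalent strain), VTK export and a
    small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
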