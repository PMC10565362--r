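Package: gravfm
Title: Nonlinear Virtual Fields Identification of Soft-Tissue Elasticity
    from Gravitational Loading
Version: 0.1.0
Authors@R:
    person("gravfm", "developers", email = "gravfm@example.org",
           role = c("aut", "cre"))
Description: Identifies compressible one-term Ogden material parameters
    (shear modulus, strain-stiffening exponent, bulk modulus) of a soft
    organ from a full-field displacement measurement under a known
    gravitational body load, using a nonlinear virtual fields method: the
    virtual-power equilibrium gap between internal stresses (computed from
    the measured deformation) and the external body-force power is
    minimised over the material parameters. Includes tetrahedral mesh I/O
    (Gmsh, legacy VTK, minimal FEBio XML), large-deformation element
    kinematics, generation of parameter-targeted virtual fields by
    fixed-boundary small-load finite-element solves, Levenberg-Marquardt
    and Nelder-Mead identification with multi-start and random landscape
    sweeps, noise-injection analyses, and a total-Lagrangian nonlinear
    forward solver for fully synthetic verification data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
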