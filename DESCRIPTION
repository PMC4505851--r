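Package: loopstring
Title: String-Method Pathways and Restrained Dynamics for Loop
    Secondary-Structure Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising slow secondary-structure transitions in
    short inter-helical protein loops that wrap onto or unwrap from a helix end,
    as seen between the outward- and inward-facing states of LeuT-fold
    transporters. Provides backbone torsion deviation maps, Kabsch
    superposition and RMSD series, dynamic cross-correlation, H-bond distance
    monitors and quaternion rigid-pose interpolation; a Langevin dynamics
    engine with Cartesian, RMSD (targeted molecular dynamics), centre and
    orientation-angle restraints; string-method refinement of transition
    pathways with Hamiltonian replica exchange and free-energy profiles by
    mean-force integration; and loop-driven protocols that advance Cartesian
    restraint frames along an interpolated pose pathway. Synthetic systems (a
    two-well 2D potential with locatable critical points and a toy loop chain
    with designed wrapped/unwrapped endpoint states) support validation of
    every component against independent oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
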