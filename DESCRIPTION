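Package: tubestress
Title: Local Stress Analysis of Cylindrically Curved Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for computing and analysing the local (Irving-Kirkwood-Noll)
    stress tensor in lipid membranes, with emphasis on cylindrically curved
    bilayers. Provides a portable stress-grid file format, a grid-based
    Irving-Kirkwood stress calculator for toy particle systems with pairwise
    central forces, per-voxel rotation to cylindrical tensor components and
    radial shell binning, lateral-stress anisotropy and maximum-shear
    profiles, the radial mechanical-equilibrium check, block-averaged
    bootstrap confidence bands, a continuum-elasticity model of monolayer
    lateral fluidity (local versus global fluidity) with finite-strain
    cylindrical bending, inversion for the depth-resolved lateral shear
    modulus, and synthetic stress-field generators with stored ground truth.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
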