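Package: diamondpack
Title: Structural Inference for Diamond-Like Disordered Sphere Packings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising low-density, tetrahedrally coordinated
    ("diamond-like") disordered packings of dielectric spheres such as the
    chitin sphere assemblies that colour longhorn-beetle scales. Provides a
    tetrahedral patchy-particle Langevin sedimentation simulator, reference
    lattice builders and a growth-and-quench jamming generator, contact-number
    and packing-fraction statistics with a configurable gap tolerance,
    Steinhardt bond-orientational order parameters (plain and
    neighbourhood-averaged q4/q6) with reference-structure classification,
    small-angle X-ray scattering forward models (polydisperse sphere form
    factor with Percus-Yevick and Baxter sticky-hard-sphere structure factors,
    plus a Debye-sum oracle) and least-squares fitting, and a synthetic
    tomogram emulator (voxelization, shrinkage/deformation degradation,
    distance-transform + watershed sphere extraction) so the full
    tomogram-to-statistics chain can be exercised without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
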