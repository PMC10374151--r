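Package: bonefoam
Title: Density-Dependent Crushable-Foam Plasticity for Femoral Bone
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration, characterization and simulation tools for an isotropic
    crushable foam (ICF) constitutive model of human femoral bone driven by
    CT-derived bone mineral density (BMD). Converts Hounsfield units to BMD via
    phantom calibration, maps BMD to complete elastoplastic material parameter
    sets through continuous or discontinuous power laws and a piecewise strength
    ratio, integrates the ICF yield surface (elliptical in pressure-deviator
    space, associated flow, hardening/softening) and a softening von Mises
    comparator at the material point, reduces compression test records
    (0.2 percent offset yield, elastic modulus, hydrostatic conversion), refits
    BMD power laws from specimen populations, and runs a small nonlinear voxel
    hexahedral finite-element solver for uniaxial and confined compression of
    cylindrical specimens. Includes seeded synthetic-data generators for
    specimen populations, test curves and voxel CT cylinders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
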