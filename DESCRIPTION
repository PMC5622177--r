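Package: vertefem
Title: Specimen-Specific Image-Based Finite Element Models of Vertebrae
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for specimen-specific continuum-level finite
    element modelling of vertebral bodies from micro-CT-like image volumes.
    Covers 8-bit grayscale normalisation, cross-scanner grayscale conversion,
    partial-volume down-sampling to continuum resolution, bone/cement
    segmentation, voxel-aligned hexahedral meshing with a linear
    grayscale-to-modulus material law E = alpha * GS, small-strain linear
    elastic simulation of axial compression with a rigid tied loading plate,
    extraction of experimental apparent stiffness as the maximal slope over a
    0.6 mm moving window, species-level Brent calibration of the conversion
    factor alpha against normalised stiffness RMSE, trabecular morphometry
    (bone volume fraction, mean-intercept-length fabric tensor, degree of
    anisotropy, trabecular orientation), and agreement statistics (Lin's
    concordance correlation, Bland-Altman). Includes seeded synthetic vertebra
    phantoms and load-displacement curve generators so the full pipeline is
    testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'abaqus.R'
    'calibration.R'
    'fe_solver.R'
    'image_ops.R'
    'io.R'
    'mech_curves.R'
    'meshing.R'
    'morphometry.R'
    'phantom.R'
    'pipeline.R'
    'utils.R'
    'workflow_stats.R'
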