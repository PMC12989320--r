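Package: imrtdose
Title: Dose Prediction, Fluence-Map Optimization, and Plan Evaluation for IMRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for intensity-modulated radiation therapy
    (IMRT) treatment-plan modelling. Encodes patient anatomy and arbitrary
    coplanar multi-beam geometry into three generalized input channels
    (normalized prescription, weighted avoidance, beam trace), computes 3D
    dose with a fluence-convolution broad-beam engine (beam's-eye-view
    conformal apertures, ray-traced radiological depth, percentage-depth-dose
    lookup), predicts dose with a compact voxel-wise regression network
    trained under the Huber loss, verifies physical feasibility by
    reference-guided fluence-map optimization with non-negative beamlet
    intensities, and evaluates agreement with 3D gamma passing rates
    (3%/2 mm, 10% low-dose threshold), dose-volume histogram metrics and
    mean absolute percentage errors. Includes a seeded synthetic-phantom
    generator producing optimization-based label doses for end-to-end
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
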