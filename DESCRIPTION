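Package: cbctdose
Title: Dose Evaluation on Corrected Cone-Beam CT for Breast Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate whether corrected cone-beam CT (CBCT) images
    support accurate photon dose evaluation for breast radiotherapy patients
    with anatomical change. Implements a synthetic thorax phantom with
    controllable breast deformation and a phenomenological CBCT artifact
    simulator (HU-scale distortion, low-frequency shading, noise, limited
    field of view); three CBCT correction methods (multilevel-threshold
    density override, iterative analytical grey-level conversion with
    shading correction, and virtual CT construction); rigid and demons
    deformable registration with a ground-truth bypass; Hounsfield-unit
    accuracy metrics; a primary-fluence ray-tracing dose surrogate with DVH
    statistics; global 3-D gamma analysis; and a mean-heart-dose based
    acute coronary event risk model.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
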