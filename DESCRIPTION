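Package: vfadose
Title: Whole-Volume Gel Dosimetry via Variable-Flip-Angle R1 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for MRI-based Fricke gel dosimetry of ion
    beams. Implements voxel-wise longitudinal relaxation rate (R1) mapping
    from variable-flip-angle spoiled gradient echo (VFA-SPGR) magnitude
    volumes, Fe3+ reference-gel calibration and radiation-chemical-yield
    computation, dose-difference (delta-R1) depth-dose analysis with
    Bragg-peak localization and percentage-depth-dose comparison against
    ionization-chamber reference curves, and a synthetic carbon-beam
    phantom generator with k-space truncation (Gibbs ringing) and Rician
    noise simulation so the whole chain can be validated without scanner
    data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
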