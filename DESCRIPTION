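Package: mrdose
Title: Synthetic-CT-Free Photon Dose Calculation for MR-Guided Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Dose-calculation toolkit for 0.35 T MR-guided radiotherapy
    research. Provides air-cavity correction of deformed CT images,
    beam's-eye-view (BEV) cuboid geometry for transverse photon beams, a
    sequence (LSTM) dose engine with a 3D U-Net air-cavity segmenter
    trained with a cavity-weighted loss, 3D gamma-index and DVH
    evaluation, beamlet-based nine-field plan optimization, and a
    synthetic pelvis phantom with an analytic magnetic-field beam-dose
    oracle so the full pipeline runs without patient data or Monte Carlo
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
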