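Package: priorfov
Title: Truncation-Artifact Correction and Field-of-View Extension for Megavoltage CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting projection-truncation artifacts in
    megavoltage CT (MVCT) and extending the scan field of view. Implements
    sinogram-domain water-cylinder extrapolation with a mass-consistency
    diagnostic, parallel- and fan-beam forward projection with filtered
    back-projection, a contrastive-learning GAN that translates kilovoltage
    CT into synthetic MVCT, and a Swin-transformer window-attention
    inpainting network that fuses the pre-corrected reconstruction with the
    synthetic-MVCT prior. Ships a seeded generator of paired kV/MV phantom
    slices, rigid registration, and masked MAE/RMSE/SSIM evaluation so the
    whole pipeline can be exercised end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
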