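Package: dwianomaly
Title: Unsupervised Anomaly Detection in Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection and delineation of diffusion anomalies
    (e.g. glioma-altered tissue) in diffusion-weighted MRI. Implements two
    deep anomaly-detection models trained only on healthy scans: a denoising
    variational autoencoder whose input-output residual map scores anomalies,
    and a two-stage reconstruction plus discrimination network trained on
    synthetically corrupted volumes (ellipsoidal just-out-of-distribution
    noise patches). Includes a diffusion-tensor phantom generator, the noise
    injection machinery, five threshold-selection strategies (fixed, Otsu,
    pooled-maximum, Youden, Dice-optimal), 3D morphological post-processing,
    and masked Dice/ROC-AUC evaluation with k-fold cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
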