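Package: zeaxspec
Title: Multispectral Quantification of Zeaxanthin in Chili Pepper Exocarp
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for predicting zeaxanthin content in chili pepper
    (Capsicum annuum) exocarp from 19-band multispectral reflectance
    (365-970 nm) in the presence of strong spectral multicollinearity with
    capsanthin.  Provides a synthetic spectra-plus-chemistry generator with
    the statistical structure of ripe-pepper populations, continuous wavelet
    preprocessing, KMO/Bartlett/PCA-based characteristic-wavelength
    selection, a compact one-dimensional convolutional spectral regressor,
    a multimodal chemical-spectral fusion model (MCSF) and its
    composite-red-index feature-replacement variant (MCSF-FR), baseline
    learners (random forest, backpropagation network, partial least
    squares), stratified splitting with Kolmogorov-Smirnov consistency
    checks, regression metrics (R2, RMSE, RPD), and an interpretability
    suite (ablation, chemical-correlation sensitivity, 1-D Grad-CAM band
    saliency, t-SNE feature-space diagnostics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
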