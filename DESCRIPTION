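Package: deepehr
Title: Patient Representation Learning from Longitudinal EHR Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns fixed-length "Deep Feature" patient vectors from
    variable-length sequences of multi-hot inpatient records with a
    denoising GRU sequence autoencoder, and evaluates them against
    window-based statistical representations (averaged raw features, PCA,
    k-means, Gaussian mixtures) on in-hospital mortality prediction,
    per-comorbidity and top-k comorbidity prediction, and a t-SNE
    grid-mortality similarity analysis. Includes a synthetic longitudinal
    EHR generator with latent disease-progression states so the whole
    pipeline runs without access to protected clinical data.
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
    e1071,
    mclust,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    xgboost,
    class,
    pROC,
    withr
Config/testthat/edition: 3
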