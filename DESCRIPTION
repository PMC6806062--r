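Package: physioload
Title: Expertise Classification from Wearable ECG and GSR Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for classifying user expertise (expert vs
    novice) from wearable electrocardiogram (ECG) and galvanic skin response
    (GSR) recordings. Implements Pan-Tompkins-style QRS detection, skin
    conductance response (SCR) event detection, windowed heart-rate-variability
    and electrodermal feature extraction (time domain and Lomb-periodogram
    frequency domain) with baseline-ratio normalization, LASSO feature ranking,
    leave-one-subject-out classifier evaluation (SVM, decision tree, random
    forest, KNN), and t-SNE feature-space projection. Includes a synthetic
    two-class ECG+GSR cohort generator with complete ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    signal,
    glmnet,
    e1071,
    rpart,
    randomForest,
    class,
    cluster,
    Rtsne,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
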