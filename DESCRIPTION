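Package: seedstage
Title: Detection of Early Seedling Development Stages from Top-View Time-Lapse Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for extracting the kinetics of early seedling
    development (emergence, cotyledon opening, first leaf) from top-view tray
    time-lapses. Includes a synthetic tray time-lapse generator with known
    per-pot stage schedules, tray rectification and pot extraction (landmark
    detection, Fourier-PCA orientation estimation, projective rectification),
    HSV background removal, four frame-classification strategies (multi-class
    CNN, chained two-class CNNs, CNN-LSTM with peephole gates, ConvLSTM) built
    on an internal BLAS-backed neural network engine, ontology-aware temporal
    smoothing of predicted stage sequences, and confusion-matrix based
    evaluation with per-class F1 and summary metrics. Tabular results are
    returned as tibbles with broom-style tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
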