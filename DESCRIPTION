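Package: semgclean
Title: ECG Artifact Removal from Surface EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Removes electrocardiographic (ECG) artifacts from multichannel
    surface electromyography (sEMG) recordings. Implements multi-level
    discrete wavelet denoising with hard, soft and an improved continuous
    threshold rule, PCA whitening, negentropy-based FastICA with a
    steepest-descent initialisation refinement, fuzzy-entropy scoring of the
    separated components, and a sorted-entropy gap rule that identifies and
    eliminates ECG components before reconstructing the cleaned sEMG.
    Includes a seeded synthetic-signal generator (bursting band-limited sEMG,
    Gaussian-bump PQRST ECG trains, mains/baseline/white-noise interference,
    linear instantaneous mixing) so the full pipeline is testable without
    recorded data, evaluation metrics (correlation coefficient, RMSE,
    signal-to-noise ratio, relative error, Amari index), delimited-text
    multichannel I/O and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
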