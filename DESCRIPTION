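Package: fractalBOLD
Title: Fractal Scaling and Detrended Cross-Correlation Analysis of BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the fractal organisation of regional fMRI
    BOLD time series and their cross-correlation structure. Implements
    detrended fluctuation analysis (DFA) with configurable polynomial
    detrending, periodogram-based spectral exponent estimation, Mexican-hat
    wavelet scalograms, the q-dependent detrended cross-correlation
    coefficient rho(q,s), and ensemble eigenanalysis of correlation matrices
    with reflection-aware Ward clustering of eigenvectors. Includes
    event-locked phase segmentation of task sessions, shuffled-segment
    resting-state controls, and a synthetic-data module (exact-covariance
    fractional Gaussian noise, 1/f^beta signals, correlated region blocks,
    trial schedules) providing known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
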