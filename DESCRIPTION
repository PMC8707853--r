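Package: nircal
Title: NIR Calibration of Potato Quality Parameters by Modified Partial
    Least Squares
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric calibration workflow for predicting potato tuber
    dry matter and reducing sugars from 900-1700 nm near-infrared diffuse
    reflectance spectra. Implements spectral preprocessing (standard normal
    variate, multiplicative scatter correction, detrending and the four-digit
    derivative/gap/smoothing math-treatment code), modified partial least
    squares (MPLS) regression with per-factor residual standardization,
    Mahalanobis GH and standardized chemical residual (T) outlier
    elimination, six-subset cross-validation with factor selection,
    treatment grid ranking, and external validation statistics (SEP, SEP(C),
    bias, paired t-test). A synthetic spectra generator emulating the
    two-cultivar study design makes the whole pipeline testable without
    instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
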