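Package: hofc
Title: Higher-Order Functional Connectivity via Multivariate Cumulants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies genuine (non-redundant) higher-order functional
    connectivity between brain-region time series using multivariate
    cumulants: coskewness (third order), cokurtosis (fourth order), and a
    Gaussian-corrected version of edge functional connectivity.  Includes a
    non-Gaussian first-order vector-autoregressive generative model with
    skew-normal or Student-t innovations and closed-form ground-truth
    connectivities, block-bootstrap and coherent phase-randomization
    inference for autocorrelated signals, simulation harnesses for bias,
    standard-error, detection-probability and bootstrap-calibration studies,
    and seed-based higher-order connectivity mapping for multi-subject data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
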