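Package: xrfnet
Title: Neural-Network Calibration for Trace Arsenic by ED-XRF Under Lead
    Spectral Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies trace arsenic in rice-based foods from
    energy-dispersive X-ray fluorescence (ED-XRF) spectra in the presence of
    lead spectral interference at the As K-alpha / Pb L-alpha overlap near
    10.5 keV.  Provides a physics-grounded forward simulator of benchtop
    ED-XRF spectra of spiked rice pellets (Gaussian detector response,
    exponential matrix continuum, Poisson counting noise), a feed-forward
    neural-network calibration engine (two hidden layers, ReLU, dropout,
    full-batch Adam, best-checkpoint early stopping) with residual z-score
    outlier screening, and the full method-performance battery: calibration
    R-squared and standard error of calibration, Eurachem replicate-based
    detection and quantification limits, predictive bias, and a +/-20 percent
    validation-agreement protocol with per-category error summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
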