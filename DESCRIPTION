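Package: painkf
Title: Kalman-Filter Models of Pain Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulators for single-layer and hierarchical Kalman-filter models
    of pain perception. The perceived pain is the posterior estimate of a
    latent tissue-damage state obtained by fusing an internal-model prediction
    (the expected pain) with truncated-Gaussian sensory input on an 11-point
    scale; a second, hierarchical Kalman filter adapts the internal-model
    parameters from the prediction error between perceived and expected pain.
    Includes scenario engines for placebo/nocebo conditioning, chronic pain,
    spontaneous neuropathic pain, pain-history risk factors and offset
    analgesia, with replicate aggregation (median/IQR over simulation runs,
    mean/SE over simulated individuals), tidy tibble outputs, ggplot2
    autoplot methods, and delimited-text writers with reproducible run
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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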