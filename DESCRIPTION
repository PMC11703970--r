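Package: bdstop
Title: Bayesian Dynamic Stopping for Code-Modulated Visual Evoked
    Potential Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evoked-response brain-computer interfaces that decide,
    trial by trial, when enough electroencephalography (EEG) has been seen to
    emit a classification. Implements Bayesian dynamic stopping: a Gaussian
    generative model of template-matching scores whose Bayes-risk-minimizing
    likelihood-ratio test yields a per-window decision boundary controlled by a
    single false-positive/false-negative cost ratio. Includes pseudo-random
    stimulus code generation (maximum-length sequences, Gold code families,
    two-duration flash modulation, low-correlation subset selection, event
    structure matrices), reconvolution canonical correlation analysis for
    learning spatial filters and temporal responses, baseline stopping rules
    (fixed-length, static decoding-curve rules, calibrated margin, Beta
    distribution), a synthetic c-VEP trial generator with known ground truth,
    and a decision-level evaluation harness (precision, recall, specificity,
    F-score, information transfer rate, cross-validated hyper-parameter
    sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
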