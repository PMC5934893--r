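Package: rsvpauth
Title: EEG Identity Authentication from Self-Face Rapid Serial Visual Presentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and classification pipeline for
    EEG-based identity authentication built on the self-face versus
    non-self-face rapid serial visual presentation (RSVP) paradigm.
    Generates RSVP stimulus schedules and synthetic multi-channel EEG with
    subject-specific event-related potential (ERP) signatures, implements
    the acquisition signal chain (Chebyshev low-pass filtering, decimation
    by block averaging, epoching with baseline correction), selects
    subject-specific channels with the pointwise biserial correlation
    coefficient, classifies user versus imposter trials with hierarchical
    discriminant component analysis (spatial Fisher discriminant weights
    per time window combined by penalized logistic regression), and
    evaluates authentication accuracy, false acceptance rate and false
    rejection rate under two imposter scenarios and a cross-session
    stability protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
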