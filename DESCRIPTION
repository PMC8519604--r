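Package: eegmsda
Title: Multi-Source Domain Adaptation for Cross-Subject EEG Fatigue
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying mental fatigue from multi-channel EEG
    across subjects without labels for the test subject.  Implements a
    band-power preprocessing pipeline (segmentation, zero-phase band-pass
    filtering, one-sided log power spectral density at integer
    frequencies, theta/alpha/beta feature assembly), a multi-source
    unsupervised domain-adaptation model with a shared feature extractor,
    per-source subnetworks and classifier heads, a label-conditional
    weighted maximum mean discrepancy alignment loss, a
    similarity-weighted classifier-discrepancy loss, a
    leave-one-subject-out evaluation harness, and a synthetic
    multi-subject EEG cohort simulator for end-to-end testing without
    access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
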