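Package: remotewear
Title: Wrist Accelerometry, Symptom-Triggered Sampling, and Engagement
    Accounting for Remote Frailty Monitoring
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A device-agnostic analytics toolkit for remote monitoring of
    older adults with wrist-worn accelerometers, connected scales and
    tablet-administered surveys. Converts raw 10 Hz triaxial counts to
    calibrated 1-second epochs, flags non-wear, detects steps with a
    two-stage moving-window/peak-run algorithm, and derives frailty-aligned
    mobility metrics (daily steps, 90th-percentile cadence, longest walking
    bout, variance-based Activity Index) under per-24-hour validity rules.
    Also implements the symptom-triggered prompt scheduler (self-rated
    health surveys, symptom follow-up chains, weekly scale sessions,
    conditional watch-monitoring prompts), adherence and engagement
    reporting including participant-attributable completion, System
    Usability Scale scoring, geriatric-assessment change flags, and a
    synthetic-data generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
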