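Package: spiroqc
Title: Quality Assurance for Forced Expiratory Spirometry Maneuvers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quality assurance for spirometry sessions. Computes
    forced expiratory indices (FEV1, FVC, PEF, back-extrapolated volume,
    forced expiratory time, end-of-forced-expiration plateau) from
    volume-time curves sampled on a 0.01-s grid, detects and localizes
    common maneuver artifacts (cough, glottic closure, device flutter,
    early termination, extra breath, hesitant start) with deterministic
    signal-domain rules, combines rule checks and artifact findings into
    per-maneuver acceptability and usability verdicts and session-level
    A-F/U quality grades with operator warnings and patient guidance, and
    ships a physiologically shaped maneuver simulator with ground-truth
    labels plus classification-metric and proportion-trend evaluation
    utilities for benchmarking the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
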