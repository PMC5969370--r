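Package: mptt24
Title: Primary Major-Incident Triage Tools and Their Diagnostic Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the MPTT-24 primary major-incident triage algorithm
    together with its comparators (the original Modified Physiological Triage
    Tool and the UK Military Sieve), a life-saving-intervention definition of
    the Priority One casualty, and the diagnostic-accuracy machinery used to
    compare triage tools: sensitivity, specificity, positive predictive value
    and diagnostic odds ratio with 95% confidence intervals, undertriage and
    overtriage rates, and the paired McNemar test. A synthetic cohort
    generator produces trauma-registry-like casualty populations with known
    ground truth and exactly computable operating points, so the whole
    pipeline can be exercised and validated without access to governed
    registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
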