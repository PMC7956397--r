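Package: hfital
Title: Posture and Physical-Activity Classification for Thigh-Worn
    Accelerometry in Hospitalized Patients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies sedentary, standing and dynamic activity and detects
    postural transitions from raw thigh-worn tri-axial accelerometer
    recordings (25 Hz, +/-8 g). Implements the adjustable window-based
    decision-tree algorithm in its baseline form (MOXAL: activity-first tree,
    tri-axial activity counts) and its optimized form for hospitalized
    patients (HFITAL: posture-first tree, single anterior-posterior axis
    counts), together with the full validation-metric suite (per-activity and
    transition confusion matrices, sensitivity, specificity, accuracy,
    percentage error and absolute percentage error, cohort medians), a
    grid-search optimizer over window size and activity threshold, and a
    seeded synthetic-recording generator with ground-truth annotations for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
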