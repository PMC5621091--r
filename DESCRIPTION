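Package: harsvm
Title: Energy-Efficient Activity Recognition with Hierarchical SVMs and
    Context Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognises six everyday activities (sitting, standing, walking,
    running, climbing upstairs, going downstairs) from low-sampling-rate
    tri-axial accelerometer and barometer streams. Provides fixed-window
    feature extraction (signed and absolute barometric pressure change,
    per-axis acceleration means, and a motion-wave statistic), a
    hierarchical binary support-vector-machine classifier whose tree is
    built by k-means-guided splits ranked by split purity and class
    balance, a sliding-window majority-vote smoother with its closed-form
    binomial accuracy model, sampling-rate/window-length equivalence
    utilities, a seeded synthetic session generator, and evaluation
    helpers (confusion matrices, per-class and macro accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
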