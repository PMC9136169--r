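Package: gaitknn
Title: Gait Stability and Symmetry Features for Fall-Risk Classification
    from Bilateral Ankle Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing fall risk in older adults
    from bilateral ankle tri-axial accelerometry. Raw acceleration is low-pass
    filtered (8th-order zero-phase Butterworth, 20 Hz), heel strikes are
    detected from anterior-posterior valleys, gait cycles are segmented and
    time-normalized, and sliding-window normalized cross-correlation (NCC)
    series quantify gait stability (left-to-left, right-to-right) and gait
    symmetry (left-to-right, right-to-left). Mean and variability summaries of
    the four NCC series form an 8-feature gait-pattern vector classified with
    a deterministic k-nearest-neighbor model under stratified cross-validation.
    A seeded synthetic-cohort generator emulates quasi-periodic bilateral gait
    acceleration with configurable cycle-to-cycle jitter and left-right
    asymmetry, so the full pipeline is testable without access to clinical
    recordings.
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
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
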