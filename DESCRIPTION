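Package: jitaipa
Title: Simulation and Evaluation of Just-in-Time Adaptive Interventions for Physical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating hourly just-in-time adaptive
    interventions (JITAI) that prompt physical activity from wrist-worn
    activity-tracker data. Simulates two-week minute-level activity streams for
    a small cohort with between-person and within-person variability, diurnal
    structure, sleep and nonwear; derives personalized (week-1 mean +/- SD) and
    uniform (reference-cohort) intervention thresholds for hourly distance
    moved and sedentary time; replays the hourly prompt-decision rule on the
    :34-minute grid; and evaluates intervention effects with two-level linear
    mixed models (pre/post-hour and week-1/week-2 contrasts) including
    AIC-based random-slope selection, BMI/sex adjustment, cell means and
    Tukey-Kramer multiple-comparison adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
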