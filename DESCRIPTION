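Package: somnotype
Title: Sleep Architecture and Coping Phenotype Analysis for Rodent
    Social Defeat Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing telemetric EEG/EMG/activity recordings
    from rodent stress studies. Provides rule-based sleep staging in
    10-second epochs from delta/theta spectral ratios, EMG amplitude and
    locomotor activity; hypnogram microarchitecture metrics including
    state-time percentages by photoperiod, awakening detection,
    exaggerated motor responses at awakening, and REM-sleep
    fragmentation (single versus sequential episodes); bootstrap
    two-cluster classification of active versus passive coping phenotype
    from resident-intruder defeat latencies; mixed-design
    (between-group by repeated-time) ANOVA with Greenhouse-Geisser
    correction and Tukey HSD post hoc tests; a ground-truth synthetic
    data generator for end-to-end validation; and a study pipeline that
    orchestrates scoring, metrics, classification and statistics from a
    single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
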