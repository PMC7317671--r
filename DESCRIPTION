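Package: mtalong
Title: Longitudinal Analysis of Medial Temporal Atrophy Ratings and Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal cohorts rated on the ordinal
    medial temporal atrophy (MTA, Scheltens) scale alongside hippocampal and
    inferior lateral ventricle volumes. Provides CSF amyloid/tau (A/T)
    stratification, per-subject annual-change estimation by least squares,
    Cohen's weighted kappa inter-rater agreement, kernel-density crossover
    thresholds quantifying the sensitivity of discrete ratings to volume
    change, progression-time arithmetic, and a synthetic-cohort generator
    emulating the statistical structure of a memory-clinic study, so that
    every stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
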