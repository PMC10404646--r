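Package: sltriplet
Title: Analysis Pipeline for Triplet-Based Statistical Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Tools for designing, simulating, scoring, and analyzing
    triplet-embedded statistical learning (SL) experiments of the kind used
    to compare linguistic and nonlinguistic SL in school-aged children.
    Builds familiarization streams with embedded triplets, foils, and
    two-alternative forced-choice (2-AFC) test phases for four task
    configurations (image, letter, tone, syllable); scores target-detection
    keypress logs into hits, false alarms, and A-prime sensitivity with
    configurable exclusion rules; computes z-normed reaction-time slopes,
    2-AFC accuracies, and composite SL scores; and runs group-level
    inference (one-sample learning tests, mixed-effects models, correlation
    analyses, Fisher-z correlation comparisons, Hedges-corrected effect
    sizes, and Cousineau-Morey within-group standard errors). A behavioral
    simulator generates synthetic cohorts with known ground-truth learning
    parameters so the whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
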