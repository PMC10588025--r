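Package: rxmine
Title: Co-Prescription Pattern Mining in Pharmacy Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for discovering co-prescription patterns of
    type 2 diabetes mellitus (T2DM) patients from pharmacy-claims data lacking
    diagnosis codes. Provides rule-based claims phenotyping of T2DM (antidiabetic
    drug presence, prescriber specialty, and exclusion rules for type 1 diabetes,
    polycystic ovary syndrome, and pregnancy), attribute mapping of national drug
    codes onto the Anatomical Therapeutic Chemical (ATC) hierarchy, per-patient
    transaction construction at each ATC level with age and gender stratification,
    a from-scratch FP-Growth frequent-itemset miner with association-rule
    generation (support, confidence, lift, and a diabetic-prevalence indicator),
    diabetes-anchored rule reporting, and a seeded synthetic claims generator with
    closed-form expected rule metrics for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
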