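Package: hivprognosis
Title: External Validation of Prognostic Mortality Scores in Older People Living with HIV
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute points-based and continuous prognostic mortality
    scores for people living with HIV (the Dat'AIDS score and the VACS index
    1.0 and 2.0) from routine cohort data, and to externally validate them
    against observed 5-year all-cause mortality. Includes cohort ingestion
    with windowed baseline-value selection, clinical transforms (CKD-EPI
    eGFR, BMI, FIB-4, anaemia and CD4 banding), score engines driven by
    auditable definition assets, discrimination (Harrell's C with subgroup
    analyses), calibration (intercept and slope on the Poisson regression
    representation of a Cox model, and predicted versus observed Kaplan-Meier
    survival by risk group), hazard ratios across risk groups, head-to-head
    score comparison on common complete cases, and a synthetic cohort
    generator emulating a French cohort of people living with HIV aged 70
    years or older.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
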