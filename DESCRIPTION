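Package: oxipheno
Title: Oximetry Pattern Phenotyping for Sleep Apnea Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of nocturnal pulse-oximetry (SpO2) patterns across
    four analytic families - desaturation characteristics (ODI2-ODI5 and
    hypoxic burden), time-series distribution metrics, power-spectral-density
    band features with spectral entropy, and non-linear measures (sample
    entropy and the central tendency measure) - together with the cohort
    association protocol used to relate them to incident cardiovascular
    disease: z-standardization, group comparisons, Spearman correlation
    with the apnea-hypopnea index, covariate-adjusted Cox proportional
    hazards models with sex stratification, and Benjamini-Hochberg false
    discovery rate control within analysis families.  Includes a synthetic
    oximetry cohort simulator (signals, respiratory events, hypnograms,
    covariates and landmark survival outcomes) so the full pipeline is
    testable without access-restricted polysomnography data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
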