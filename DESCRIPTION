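Package: siascore
Title: Primary Care Scoring Algorithm and Diagnostic Accuracy Tools for
    SIAscopic Skin Lesion Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements rule-based diagnostic scoring of pigmented skin
    lesions from expert-scored SIAscopic features: the Moncrieff scoring
    system, the Primary Care Scoring Algorithm (PCSA, which first gates out
    seborrhoeic keratoses and haemangiomas), and the 7-point melanoma
    checklist.  Provides the diagnostic-accuracy machinery used to evaluate
    such rules (confusion matrices, Wilson score intervals, ROC curves with
    trapezoidal AUC, Hanley-McNeil standard errors and correlated-AUC
    z-tests), inversion of rounded published accuracy statistics to integer
    confusion matrices, and a seeded, calibratable generator of synthetic
    lesion cohorts emulating primary-care case mix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
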