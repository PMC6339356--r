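Package: katagiri
Title: Modified Katagiri Prognostic Score and Survival Validation for Bone
    Metastases Treated with Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the modified Katagiri prognostic score (0-10 points over
    six clinical factors) and its low/intermediate/high risk stratification for
    patients receiving palliative radiotherapy for bone metastases, together
    with the survival machinery needed to validate such a score:
    Kaplan-Meier product-limit estimation, k-sample log-rank tests, and Cox
    proportional-hazards fitting by Newton-Raphson on the partial likelihood.
    Includes a seeded piecewise-exponential cohort simulator calibrated to
    published risk-group survival profiles, covariate frequencies and hazard
    ratios, a table-building validation pipeline (characteristics, univariate
    screening, multivariate models, risk-group survival rates), CSV readers
    and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
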