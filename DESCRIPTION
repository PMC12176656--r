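Package: admarkers
Title: Blood Biomarkers of Alzheimer's Disease and Incident Dementia in
    Community Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association and prediction analyses linking six blood biomarkers
    of Alzheimer's disease (the amyloid-beta 42/40 ratio, p-tau181, p-tau217,
    total tau, neurofilament light chain, and glial fibrillary acidic protein)
    to incident all-cause and Alzheimer's disease dementia in longitudinal
    community cohorts. Provides Cox proportional-hazards models with restricted
    cubic splines and quartile contrasts, Schoenfeld diagnostics, stabilized
    inverse-probability-of-dropout weighting, bootstrap Youden-index cut-point
    estimation with internal 80/20 validation, 10-year horizon classification
    metrics (AUC, sensitivity, specificity, predictive values) for single and
    combined markers, incidence rates with exact Poisson intervals, and a
    seeded Gaussian-copula cohort simulator for end-to-end testing without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
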