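Package: partsacea
Title: Partitioned Survival Cost-Utility Modelling for First-Line
    Immunochemotherapy in Metastatic NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state partitioned survival (PartSA) cost-utility model
    comparing first-line PD-L1 inhibitor (sugemalimab) plus platinum-based
    chemotherapy with chemotherapy alone in metastatic non-small cell lung
    cancer, from the Chinese health-system perspective. Provides parametric
    survival distributions (exponential, Weibull, Gompertz, log-logistic,
    log-normal), mixture and non-mixture cure models and Royston-Parmar
    splines with right-censored maximum-likelihood fitting and AIC/BIC model
    selection; a two-arm trial simulator and Guyot-style pseudo individual
    patient data reconstruction from digitized Kaplan-Meier curves; cycle-based
    state occupancy with discounted cost, life-year and QALY accrual and ICER
    computation; and one-way, probabilistic (CEAC, incremental
    cost-effectiveness scatter) and scenario sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    graphics,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
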