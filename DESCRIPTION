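Package: periomel
Title: Markov Cohort Cost-Effectiveness Models of Perioperative Versus
    Adjuvant Immunotherapy for Resectable Melanoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weekly-cycle Markov cohort models comparing perioperative with
    adjuvant immunotherapy for resectable melanoma from the US payer
    perspective: perioperative nivolumab plus ipilimumab versus adjuvant
    nivolumab in stage III disease, and perioperative versus adjuvant
    pembrolizumab in stage IIIB-IVC disease. Implements Gompertz event-free
    survival extrapolation with a cure plateau, proportional-hazards
    adjustment, six-state cohort simulation with age-dependent background
    mortality, discounted cost/QALY/life-year accrual by cost category,
    incremental cost-effectiveness and net-monetary-benefit comparison,
    one-way (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, maximum-likelihood parametric
    survival fitting with BIC selection, and pseudo individual-patient-data
    reconstruction from published Kaplan-Meier coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
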