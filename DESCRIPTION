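Package: dcisim
Title: Microsimulation of DCIS Natural History, Screening, and Overdiagnosis
Version: 0.1.0
Authors@R:
    person("Maarten", "Veldkamp", email = "m.veldkamp@example.org",
           role = c("aut", "cre"))
Description: A discrete-event microsimulation of the natural history of
    ductal carcinoma in situ (DCIS) and its progression to invasive breast
    cancer, with period-specific mammography sensitivity, US-style screening
    dissemination, and a parallel-universe counterfactual design (each woman
    is simulated with and without screening under common random numbers).
    Provides estimators for incidence tables with direct age standardization,
    mean sojourn times by exit path, progression proportions, overdiagnosis,
    chi-square goodness of fit against observed incidence, and simplex
    calibration of free natural-history parameters. A synthetic-data module
    generates life tables, dissemination schedules, and SEER-like observed
    incidence with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
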