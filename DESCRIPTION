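Package: secmal
Title: Secondary Malignancy Risk Estimation from Paired Proton and Photon
    Dose-Volume Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates radiation-induced secondary cancer risks for thoracic
    organs at risk (bilateral lungs, bilateral breasts, esophagus) from
    differential dose-volume histograms of paired proton and photon
    radiotherapy plans. Implements a linear-quadratic competition model for
    total and fatal cancer induction risk and the organ-equivalent-dose (OED)
    framework under linear, linear-exponential and plateau dose-response
    scenarios, with proton/photon relative risks as OED ratios. Includes
    plain-text DVH import/export, exact paired Wilcoxon signed-rank cohort
    statistics, and a seeded generator of synthetic paired cohorts emulating
    a mediastinal-lymphoma study population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
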