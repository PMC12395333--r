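Package: pnecres
Title: Cost-Based Prediction of No-Effect Concentrations for Antibiotic
    Resistance Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts no-effect concentrations for the selection of
    antibiotic resistance (PNEC_res) from routinely collected minimum
    inhibitory concentration (MIC) data and probabilistic estimates of
    resistance fitness costs. Implements the closed-form relation between
    the minimum selective concentration (MSC), the MIC and the cost of
    resistance under linear and power-law dose-response curves; estimation
    of growth rates, costs and empirical MSCs from competition-assay data
    using monotone Hermite splines; extraction of robust lowest MICs from
    EUCAST-style species-wise MIC distribution tables with a species
    coverage bias correction; maximum-likelihood fitting of an
    exponential-plus-Gaussian mixture to empirical resistance costs with
    bootstrap and profile-likelihood confidence intervals; and the
    combination of the lowest MIC with a cost quantile into a PNEC_res,
    replacing fixed assessment factors. Synthetic-data generators with
    known ground truth support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
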