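Package: sessiondose
Title: Indirect-Response Modelling of Mental Healthcare Session Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models depressive symptom severity as an indirect response to
    mental healthcare sessions ("session dosing"). Coaching, therapy and
    psychiatry sessions act as unit inputs into latent service compartments
    whose decaying combined mass inhibits symptom production through a
    capacity-limited (Hill-type) function. Provides a stochastic
    approximation EM (SAEM) fitter for the hierarchical nonlinear
    mixed-effects model, empirical-Bayes individual parameter estimates,
    individual weighted residual (IWRES) triage of fit quality, simulation
    and comparison of hypothetical treatment schedules, a synthetic cohort
    generator matching the structure of sparse real-world measurement-based
    care data, and a pharmacometric event-record dataset format with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
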