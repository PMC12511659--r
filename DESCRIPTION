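Package: adheretraj
Title: Adherence Trajectories from Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal medication-adherence analysis on
    administrative pharmacy-claims data: new-user cohort construction with an
    explicit attrition cascade, monthly proportion-of-days-covered (PDC)
    series from dispensing records under a one-DDD-per-day coverage
    assumption, data-driven adherence-trajectory clustering (24 longitudinal
    change measures, principal-component measure selection, k-means with a
    majority vote of cluster-validity indices), and a multinomial logistic
    model of trajectory-group determinants with stepwise AIC selection.
    Includes a synthetic claims generator with known latent trajectory
    classes so every stage of the pipeline can be exercised and validated
    without access to real patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    lubridate,
    cluster
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
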