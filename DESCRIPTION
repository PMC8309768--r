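Package: shoalmorph
Title: Behavioral and Morphometric Endpoints for Wild Zebrafish Sentinel Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes shoaling cohesion and activity endpoints from group
    swimming trajectories, landmark-based morphometrics (generalized Procrustes
    analysis, shape principal components, body-region areas) from 7-landmark
    configurations, and the two-population statistical comparisons used in
    field studies of wild zebrafish as environmental sentinels. Includes a
    synthetic-data generator producing two-site group-swimming studies and
    landmark samples with known ground truth, so every analysis stage can be
    validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
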