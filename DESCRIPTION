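Package: effspace
Title: Super-Efficiency EBM Data Envelopment Analysis and Spatial
    Econometrics for Regional Health Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-stage analysis of regional (province-level) health
    production efficiency. Stage one scores decision-making units with a
    non-oriented super-efficiency epsilon-based measure (EBM) data
    envelopment model that credits reductions in undesirable outputs such
    as medical waste and mortality, including radial and slack-based
    limiting cases and the technical/pure-technical/scale efficiency
    decomposition. Stage two quantifies spatial structure of the scores
    with global and local Moran statistics and the Getis-Ord Gi* hot-spot
    index over user-supplied or packaged contiguity weights. Stage three
    fits spatial panel econometric models (spatial lag, spatial error and
    spatial Durbin) by maximum likelihood with fixed effects, runs the
    Harris-Tzavalis unit-root, Lagrange-multiplier, Hausman, likelihood
    ratio and Wald diagnostics that drive model selection, and decomposes
    covariate impacts into direct and indirect (spillover) effects.
    Synthetic-data generators with known frontiers and known spatial
    processes support calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
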