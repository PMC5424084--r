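Package: exclophys
Title: Leaf Gas-Exchange and Understory Light Analysis for Herbivore-Exclosure Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing leaf-level gas exchange and understory light
    data from paired fenced/unfenced (herbivore exclosure) designs.
    Fits non-rectangular-hyperbola light-response curves and
    Farquhar-von Caemmerer-Berry A/Ci curves by multi-start nonlinear least
    squares, with closed-form light compensation and saturation points;
    detects the day of overstory canopy closure from a seasonal PPFD series
    via penalized-spline derivatives; quantifies treatment divergence of
    light availability with heteroscedastic linear mixed models and
    likelihood ratio tests; and reports treatment contrasts of leaf traits
    and photosynthetic parameters, including precision-weighted group means
    and percent-difference summaries. A synthetic-data generator with known
    ground truth supports parameter-recovery and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mgcv,
    nlme,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    multcomp,
    lmtest
Config/testthat/edition: 3
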