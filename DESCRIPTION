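Package: hrcentiles
Title: Reference Centile Curves and Age-Based Prediction Equations for
    Adolescent Heart Rate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing age-conditional reference centile
    curves of maximum and resting heart rate in adolescent athletes using
    the LMS (Box-Cox Cole-Green) method, and for developing and evaluating
    age-based maximum-heart-rate prediction equations. Includes a seeded
    synthetic-cohort generator that emulates the statistical structure of
    a cross-sectional adolescent soccer cohort, skinfold-based body
    composition estimators (Durnin-Womersley density, Siri body fat),
    maximum-likelihood fitting of the Box-Cox Cole-Green distribution per
    age group with spline smoothing of the L, M and S curves, percentile
    tables and z-scores, stepwise ordinary-least-squares model selection,
    and Bland-Altman agreement statistics against the Fox (220 - age) and
    Tanaka (208 - 0.7 x age) equations.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
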