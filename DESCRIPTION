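Package: edmfit
Title: Enzyme-Driven Modelling of Leaf Photosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and simulates an enzyme-driven model of leaf photosynthesis:
    an exponential law relating net CO2 assimilation to the activity of
    rate-limiting Calvin-cycle and C4-pathway enzymes, and a log-scale
    Michaelis-Menten-type saturation law relating assimilation to effective
    leaf nitrogen above a storage baseline. Provides multi-start nonlinear
    least-squares estimation with linearization-based standard errors,
    AIC/AICc model comparison against a linear alternative, digitizer-style
    CSV input/output, report tables, and a seeded synthetic-data generator
    with parameter-recovery experiments so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
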