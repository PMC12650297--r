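Package: gscompare
Title: Comparison of Stomatal Conductance Models from Leaf Gas-Exchange Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares the Ball-Woodrow-Berry, Medlyn, and
    Fick's-law-based (Ye) stomatal conductance models to leaf gas-exchange
    response curves. Parameters (g0, g1) are estimated per replicate curve by
    nonlinear least squares on net photosynthesis, scored with adjusted
    R-squared and AIC, and compared across models with one-way ANOVA and
    compact letter displays. Includes light-response fitting with saturating
    irradiance determination, a coupled photosynthesis-diffusion steady-state
    simulator of LI-6400-style measurement protocols, and ingest of logged
    gas-exchange tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
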