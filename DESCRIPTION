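Package: promstruct
Title: Structural Validity Analysis for Patient-Reported Outcome Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the structural validity of ordinal
    patient-reported outcome measures, built around the 18-item IKDC
    Subjective Knee Form. Provides maximum-likelihood exploratory factor
    analysis with Horn's parallel analysis and oblique (geomin/oblimin)
    rotation, a confirmatory covariance-structure engine for one-factor,
    correlated-factor and bifactor models with modification indices and
    nested chi-square difference tests, the standard fit battery (CFI,
    TLI, RMSEA with 90% confidence interval, SRMR), bifactor reliability
    and dimensionality indices (omega, omega-hierarchical, relative
    omega, factor determinacy, explained common variance, percent
    uncontaminated correlations), and a seeded generator of synthetic
    ordinal respondent cohorts from bifactor or correlated-factor latent
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
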