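Package: tentemix
Title: Targeted Plus Non-Targeted Effects Modelling of Radiation
    Carcinogenesis with Mixture Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose-response modelling of per-animal tumour counts induced by
    ionizing radiation, combining a linear targeted-effects (TE) term with a
    saturating non-targeted (bystander, NTE) term. Count variability is
    described by a weighted negative binomial distribution that allows both
    under- and overdispersion relative to Poisson. Provides constrained
    maximum-likelihood fitting with parameter sharing across radiation types
    and AICc model comparison, background-moment constraints that eliminate
    two parameters, dose-dependent relative biological effectiveness (RBE)
    and radiation effects ratio (RER) relative to gamma rays, Monte Carlo
    likelihood-region confidence envelopes, and incremental effect additivity
    (IEA) versus simple effect additivity (SEA) predictions for multi-ion
    mixtures such as the galactic-cosmic-ray exposure expected on a Mars
    mission. Includes a synthetic-data generator emulating the APC(1638N/+)
    mouse intestinal tumorigenesis experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
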