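Package: bmkin
Title: Bayesian Multilevel Prediction of Enzyme Kinetic Parameters with
    Calibrated Uncertainties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts values and calibrated uncertainties of enzyme kinetic
    parameters (Michaelis constants KM and turnover numbers kcat) from
    categorical predictors (substrate, EC number, reaction, protein family,
    protein identifier) using hierarchical Bayesian multilevel location-scale
    models fitted by MCMC. Includes nested group-path construction for the KM
    and kcat hierarchies, a heteroscedastic residual model with two annotation
    regimes and reaction- or organism-specific scale effects, predictive
    distributions that marginalize over unobserved hierarchy levels, joint
    sampling of correlated predictions, thermodynamic parameter balancing that
    projects independent predictions onto the Haldane-consistent manifold,
    grouped cross-validation with point and probabilistic metrics (R-squared,
    RMSE, negative expected log predictive density), uncertainty-calibration
    binning, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
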