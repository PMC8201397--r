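Package: uavfield
Title: UAV-Supported Field Experiment Analysis on Gridded Plots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for integrating dense unmanned-aerial-vehicle (UAV)
    imagery with sparse hand-harvested samples in agricultural field
    trials. Per-pixel canopy indices (vegetation cover, canopy height,
    NDVI) are regressed against quadrat harvest weights by exhaustive
    all-subsets Gaussian model search scored by AIC with Akaike weights;
    the best model predicts the trait over the whole field, predictions
    are aggregated into 25-cm grid cells with strict plot and corridor
    elimination rules, and treatment effects are tested on the dense
    cell-level predictions with linear mixed models carrying nested
    row/plot random intercepts, likelihood-ratio tests,
    reference-cultivar contrasts and marginal-effect surfaces. A
    synthetic-field simulator with known ground truth supports
    end-to-end validation, and a step-wise command-line pipeline ties
    the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    EBImage,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
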