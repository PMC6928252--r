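Package: nplsnest
Title: Nested Resampling Quality Control for Multidimensional Partial Least Squares Regression
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tri-linear (three-way) partial least squares regression (N-PLS)
    for fully crossed condition-by-time in vivo study designs, together with a
    resampling framework that classifies latent variables as robust or
    fragile. Replicated measurements are kept nested within animals: jackknife
    (leave-one-replicate-out) and subsample (leave-one-replicate-in) ensembles
    remove or retain whole animals per condition-by-time cell, with optional
    pairing of independent and dependent blocks. Includes randomization null
    models (within-condition shuffling), leave-one-condition-out
    cross-validation with RMSE-based component selection, dataset- and
    study-specific standardization with invertible state, a synthetic-data
    generator with planted tri-linear structure, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
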