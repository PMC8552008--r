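Package: gaitlatent
Title: Dimensionality Reduction of Lower-Limb Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Compares linear and nonlinear dimensionality reduction of
    lower-limb joint-angle kinematics recorded during gait. Implements
    principal component analysis on single poses, a feed-forward
    autoencoder on poses, and a bidirectional recurrent sequence
    autoencoder on one-second movement windows, together with the
    reconstruction metrics (variance accounted for, standardized RMSE),
    latent dimensional-variance distributions, and latent-space support
    vector machine classification of movement class and individual
    identity used to evaluate them. A seeded synthetic gait generator
    provides flat-ground, stair and natural-movement recordings with
    class-level and subject-level structure so the whole pipeline runs
    end to end without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
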