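Package: reachsynth
Title: Conditional GAN Synthesis and Augmentation of Post-Stroke Reaching Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes 5-second, 9-channel upper-limb reaching trajectories
    (trunk position and orientation, shoulder and elbow joint angles) with a
    conditional generative adversarial network regularized by an FFT spectral
    loss and a minibatch-discrimination layer, and evaluates the synthetic
    trials with range-of-motion statistics, t-SNE embeddings, and a
    cross-validated task-classification augmentation experiment. Includes a
    parametric minimum-jerk reach-and-return simulator with
    impairment-dependent trunk compensation so the full pipeline runs without
    any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
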