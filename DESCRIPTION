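Package: traceddm
Title: Mapping Mouse-Cursor Trajectory Measures onto Drift Diffusion Model Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to combine mouse-cursor tracking with drift diffusion
    modelling in two-alternative forced-choice tasks. Extracts eighteen
    summary measures from raw cursor trajectories, fits a three-parameter
    drift diffusion model (drift rate, threshold separation, non-decision
    time) per participant by maximum likelihood on the Wiener first-passage
    density, screens fits against synthetic parameter sets, reduces the
    measure battery by correlational screening and partial least squares
    regression with variable-importance-in-projection selection, and
    evaluates the stability of the cursor-based prediction of model
    parameters under trial subsampling via bootstrap resampling. A
    synthetic cohort generator with a parameterised motor model provides
    ground-truth data for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
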