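Package: pierisflight
Title: Stereo Videogrammetry, Flight Kinematics and Wing Morphometrics for
    Seasonal Butterflies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct three-dimensional flight trajectories of
    butterflies from paired two-dimensional camera tracks (direct linear
    transformation calibration, including wand-based calibration, and
    least-squares triangulation), to smooth trajectories with a
    constant-acceleration Kalman filter and fixed-interval smoother, and to
    derive eleven per-trajectory flight parameters (velocity, acceleration,
    advance ratio, turning acceleration and rate, sinuosity, curvature,
    ascent angle and related summaries). Companion modules provide landmark
    wing morphometrics (forewing size and shape indices, wing loading), a
    synthetic-data generator with known ground truth for every stage, and
    the comparative statistical layer used in seasonal-form studies: mixed
    models with marginal means and Tukey contrasts, PCA with iterative
    imputation, stepwise backward selection and all-subsets AICc ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
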