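Package: graspadapt
Title: Trial-by-Trial Adaptation and Perturbation Detection in
    Visuo-Haptic Grasping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse visuo-haptic size-perturbation
    grasping experiments. Builds abrupt and sinusoidal perturbation
    schedules, generates synthetic experiments (maximum grip apertures
    from a linear state-space error-correction model, 3-D marker
    trajectories, and two-alternative forced-choice size judgments),
    extracts maximum grip apertures from motion-capture trajectories
    with spline interpolation, Savitzky-Golay smoothing and
    velocity-based segmentation, fits the state-space adaptation model
    (retention, error-correction, intercept) by RMSE minimisation, fits
    cumulative-normal psychometric functions yielding points of
    subjective equality and just-noticeable differences, and provides
    the accompanying inferential toolbox (repeated-measures ANOVA,
    paired t-tests with Cohen's d, JZS Bayes factors, Deming regression,
    percentile bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
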