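Package: lamsal
Title: Laminar VASO fMRI Analysis of Visual Saliency Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of cortical-depth-resolved
    cerebral-blood-volume (VASO) fMRI responses to visual saliency.
    Provides a synthetic laminar cortex generator with configurable
    laminar-origin scenarios (parietal feedback, V1 horizontal
    connections, tecto-thalamic), BOLD-correction (BOCO) preprocessing
    with block GLMs, equi-volume cortical layering and spatial-regression
    layer unmixing, adaptive-staircase psychophysics with Weibull
    psychometric fitting, normalized saliency-sensitive response
    statistics with repeated-measures ANOVA and max-statistic permutation
    family-wise error control, layer-specific generalized
    psychophysiological interaction (gPPI) connectivity, population
    receptive field visual-field-map reconstruction, and gaze
    preprocessing with bivariate contour ellipse area fixation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
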