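# lamsal — laminar VASO fMRI analysis of visual saliency signals

`lamsal` is an R package for analysing — and, crucially, for *validating
by simulation* — cortical-depth-resolved cerebral-blood-volume (VASO)
fMRI studies of visual saliency. It is aimed at laminar-fMRI
methodologists and visual neuroscientists who want a tested,
seed-reproducible implementation of the full analysis chain:

* **Synthetic laminar cortex** (`build_column_model()`,
  `scenario_spec()`, `simulate_vaso_session()`): an equi-volume
  annular-wedge cortex for V1, V2 and IPS, with interleaved
  blood-nulled / not-nulled acquisition (paired TR 5.02 s), 30-s
  condition blocks at three foreground orientation contrasts
  (θ = 90°, 15°, 0°), and configurable laminar-origin scenarios
  (parietal feedback, V1 horizontal connections, tecto-thalamic).
* **VASO preprocessing** (`split_and_align()`, `boco_correct()`,
  `percent_signal_change()`, `fit_glm()`): ×2 temporal up-sampling with
  half-TR shift, BOLD correction by nulled/not-nulled division, per-run
  percent-signal-change scaling, block GLM with canonical HRF and
  Legendre drifts.
* **Layering** (`equivolume_boundaries()`, `unmix_layers()`,
  `select_foreground_roi()`, `roi_layer_profile()`): equi-volume depth
  compartments and spatial-regression unmixing of layer activity through
  voxel volume-fraction weights.
* **Saliency statistics** (`normalize_responses()`,
  `saliency_sensitive_response()`, `rm_anova_two_way()`,
  `brain_behavior_correlation()`): the normalized response
  `S = r / rnorm(s) * rbar` (with `rnorm(s)` the per-subject RMS over
  the 9 layer × condition cells and `rbar` its group mean), the
  saliency-sensitive response `SS = S(90°) − S(15°)`, repeated-measures
  ANOVA with Greenhouse–Geisser correction, and Pearson brain–behavior
  correlation with max-statistic permutation FWE control.
* **Connectivity** (`build_ppi_design()`, `fit_gppi()`,
  `saliency_connectivity()`): layer-specific generalized
  psychophysiological interaction without deconvolution (PPI term =
  one-TR-shifted boxcar ⊙ seed), contrasting the 90° and 15° coupling.
* **Psychophysics** (`run_staircase()`, `fit_weibull()`,
  `behavioral_saliency_sensitivity()`): 3-down-1-up staircases on
  Michelson contrast, maximum-likelihood Weibull fits, threshold at 80%
  accuracy, sensitivity `S = 1/threshold`.
* **Field maps and gaze** (`reconstruct_fieldmap()`,
  `preprocess_gaze()`, `bcea()`): Gaussian-pRF back-projection of
  laminar saliency responses into visual space; blink-cleaned,
  detrended gaze traces and the 95% bivariate contour ellipse area.

Because the deposited raw scans of such experiments are typically
unavailable, the package ships a first-class synthetic-data module whose
generative laminar scenario is known, so the *entire* pipeline is
testable end-to-end: noise-free estimation reproduces the generative
gains to machine precision, and the generative scenario is recovered
from group laminar signatures with ≥95% accuracy at realistic noise.

## Worked example

Simulate a 10-subject study under the V1-origin scenario and run the
full analysis:

```r
library(lamsal)
cfg <- study_config(n_subjects = 10, n_runs = 3, n_voxels_per_region = 30,
                    n_perm = 2000, seed = 42)
st <- run_full_study(cfg)
print(st)
```

```
Simulated laminar saliency study: scenario 'v1sh', 10 subjects
  V1  argmax SS layer: superficial (mean SS 0.182/0.282/0.582)
  V2  argmax SS layer: superficial (mean SS 0.150/0.498/0.526)
  IPS argmax SS layer: middle      (mean SS 0.194/0.557/0.253)
  inferred scenario: v1sh
  brain-behavior r (V1): 0.931 (raw p 0.0005, FWE p 0.0005)
  gPPI pathway contrasts:
    V1sup_to_IPSmid    delta 0.550, t(9) = 5.67, Holm p 0.000609
    IPSdeep_to_V1deep  delta 0.163, t(9) = 1.83, Holm p 0.101
  field-map peak depth: superficial
```

Reading the output: the group saliency-sensitive response `SS` per layer
(deep/middle/superficial, in % signal change) peaks in the superficial
layers of V1 and the middle layers of IPS — the feedforward signature of
a V1 origin, which the classifier returns as `v1sh`. Behavioural
saliency sensitivity correlates with V1-superficial `SS` across subjects
(permutation-FWE-corrected), the feedforward gPPI pathway carries a
significant 90°-vs-15° coupling difference while the feedback pathway
does not, and the back-projected visual-field map is strongest at the
superficial depth. The depth ANOVA on `SS` in V1
(`st$group$V1$anova_ss`) gives F(2, 18) = 57.1 with Mauchly p = 0.37
(sphericity not violated, uncorrected p reported).

## Package layout

```
R/                 implementation (one file per analysis stage)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance.R (reproducibility entry point)
vignettes/         methods vignette: models, parameters, design choices
```
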