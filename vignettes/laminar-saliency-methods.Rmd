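---
title: "Methods: simulating and analysing laminar VASO responses to visual saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing laminar VASO responses to visual saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamsal)
```

# The scientific problem

Where in the visual system is bottom-up saliency computed? Three candidate
origins make distinct predictions about how saliency-sensitive activity
should distribute across the cortical *depth* of early visual cortex (V1)
and the intraparietal sulcus (IPS):

* **Parietal feedback** — saliency computed in parietal cortex and fed
  back: cortico-cortical feedback terminates outside layer 4, so
  saliency signals should dominate the *deep* layers of IPS and the
  deep/superficial layers of V1.
* **V1 horizontal connections** — saliency computed by intracortical
  (iso-feature suppression) circuitry: strongest in the *superficial*
  layers of V1, relayed feedforward into the *middle* (granular,
  input-recipient) layers of IPS.
* **Tecto-thalamic** — saliency of collicular origin relayed through the
  thalamus: strongest in the *middle and superficial* layers of both
  cortical regions.

Cortical-depth-resolved CBV-weighted fMRI (VASO) can measure these laminar
profiles. `lamsal` implements the complete analysis chain for such an
experiment — BOLD-corrected percent-signal-change estimation, equi-volume
layering and layer unmixing, the normalized saliency-sensitive response
and its statistics, layer-specific gPPI connectivity, pRF field-map
reconstruction, psychophysics, and eye-tracking metrics — together with a
synthetic laminar cortex whose generative laminar scenario is known, so
that the whole chain can be validated by scenario recovery without any
real data.

# The synthetic cortex and its forward model

## Geometry

`build_column_model()` models each region (V1, V2, IPS) as an annular
wedge of grey matter between a white-matter radius and a pial radius
(defaults 10 and 12 mm: 2 mm cortical thickness with moderate curvature).
Laminar boundaries follow the equi-volume principle: a boundary at
cumulative volume fraction $\alpha$ sits at

$$r(\alpha) = \sqrt{\alpha\, r_\mathrm{pial}^2 + (1-\alpha)\, r_\mathrm{wm}^2},$$

so each of the deep / middle / superficial compartments encloses the same
cortical volume regardless of curvature (a spherical-shell variant with
cube roots is available via `model = "shell"`). The wedge is intersected
with a square voxel grid (voxel edge one quarter of the thickness,
refined until the requested voxel count is reached) and each voxel
receives a volume-fraction weight vector over
{WM, CSF, deep, middle, superficial} by regular 10×10 subsampling of the
voxel area. These weights are exactly what the layer-unmixing step
regresses against, mirroring how real laminar studies compute per-voxel
layer weights from high-resolution surfaces.

## Scenarios and amplitudes

`scenario_spec()` encodes a laminar origin as a region × layer ×
orientation-contrast gain array in percent signal change. The published
hypotheses fix only the *orderings* of laminar amplitudes, so the default
numbers encode those orderings qualitatively
(e.g. the V1-origin scenario: V1 deep/middle/superficial = 0.3/0.4/1.0,
IPS = 0.3/1.0/0.4 at 90°); the 15° condition is the 90° pattern scaled by
0.4, and the 0° (uniform texture) condition is a flat 0.25 — responses at
peri-threshold amplitudes typical of sub-millimetre VASO. All gains are
configurable and serialisable to YAML.

## Signal generation

`simulate_vaso_session()` produces an interleaved blood-nulled /
not-nulled series at a paired TR of 5.02 s (frame interval 2.51 s), with
30-s condition blocks separated by 15-s fixation, 6 blocks per 270-s run.
Per voxel the CBV amplitude is the scenario gain mixed through the
voxel's grey-matter weights. Condition waveforms are block boxcars
convolved with a canonical double-gamma HRF (peak 5 s, undershoot 15 s,
ratio 6, unit integral so a block plateaus at the neural amplitude).
Activation *decreases* the nulled signal (VASO physics); the not-nulled
channel carries a BOLD-like response (`bold_scale` × the CBV gain,
optionally with a linear-in-depth superficial bias emulating draining
veins, off by default), and the same BOLD factor multiplies the nulled
frames as the T2* contamination that BOLD correction must remove. Noise
is i.i.d. Gaussian per frame (default SD 0.5% signal change) plus
per-run Legendre polynomial drift up to order 3.

Two numerical choices matter downstream:

* **Amplitude convention.** Waveforms are centred so that the run mean
  of the *preprocessed* series equals the baseline; amplitudes are
  therefore exact percent signal change under the pipeline's
  run-mean-baseline scaling.
* **Resampling-consistent regressors.** GLM condition regressors are
  built on the native acquisition grid and passed through the same ×2 /
  half-TR linear resampling as the data. Together these make the
  noise-free pipeline an exact inverse of the forward model: estimated
  layer × condition responses equal the generative gains to machine
  precision (the test suite asserts 1e-4; observed error is ~1e-15).

With the BOLD channel enabled, BOCO cancellation is exact only up to the
linear-resampling error of the division's denominator (~0.03% at default
amplitudes) — a genuine property of the nulled/not-nulled method, not of
this implementation.

# Preprocessing and estimation

`split_and_align()` separates the two streams and up-samples each by 2
with a half-paired-TR shift (linear interpolation, edge-hold at run
boundaries, runs aligned independently). Linear interpolation is exact on
degree-1 signals; for a sinusoid with period 8 paired TRs its relative
RMS error is ~6% (bounded by $(\omega h)^2/8$) — smooth haemodynamic
responses sit well below that frequency.

`boco_correct()` divides nulled by not-nulled, masking voxels with
nonpositive denominators; `percent_signal_change()` scales per run about
the run-mean baseline, and `sign = "cbv"` negates the VASO decrease so
CBV responses are positive. `fit_glm()` is ordinary least squares with
per-run intercepts and Legendre drifts (order 3 by default, matching the
generative drift basis) and optional motion columns; rank deficiencies
are reported by column name.

`unmix_layers()` solves voxel amplitudes against the voxel × compartment
weight matrix by least squares — the spatial-regression reading of layer
unmixing; WM and CSF are carried as nuisance compartments and only the
grey-matter layers are reported. No nonnegativity constraint is imposed
(responses can legitimately be negative in percent change). ROI selection
(`select_foreground_roi()`) thresholds the localizer GLM at one-sided
p < 0.05 (uncorrected) with positive amplitude, intersected with the
anatomical label, exactly as foreground ROIs are defined in practice.

# Saliency statistics

For subject $s$, layer $l$ and orientation contrast $\theta$, with raw
CBV response $r(s,l,\theta)$:

$$r_\mathrm{norm}(s) = \sqrt{\tfrac{1}{9}\sum_{l,\theta} r(s,l,\theta)^2},
\qquad \bar r = \tfrac{1}{N}\sum_s r_\mathrm{norm}(s),$$
$$S_\mathrm{fMRI}(s,l,\theta) = \frac{r(s,l,\theta)}{r_\mathrm{norm}(s)}\,\bar r,
\qquad SS_\mathrm{fMRI}(s,l) = S_\mathrm{fMRI}(s,l,90^\circ) - S_\mathrm{fMRI}(s,l,15^\circ).$$

Normalization removes per-subject gain (any positive rescaling of a
subject's responses leaves $S_\mathrm{fMRI}$ unchanged) while preserving
the group scale: every subject's RMS over the nine cells equals
$\bar r$ exactly — an identity the tests verify on random inputs. The
saliency-sensitive response uses the 15° condition as reference so that
the partial-volume background-suppression component common to both
foreground conditions cancels.

Inference uses within-subject ANOVA (via the multivariate route of
`car::Anova`, reporting Mauchly's sphericity test and applying the
Greenhouse-Geisser correction when Mauchly's p < 0.05), paired t tests
for three-level follow-ups, and Holm correction where a family of
pathways is tested. `anova_power_sim()` reproduces the design's power
calculation: Cohen's f is measured against the total within-cell SD with
the intraclass correlation fixing the subject variance (f = 0.4,
$\rho$ = 0.5, n = 20 gives noncentrality $f^2 N k/(1-\rho) = 19.2$ and
~97% power, comfortably above the 90% the design targets).

Brain–behavior correlation uses max-statistic permutation FWE: the
subject correspondence is shuffled, Pearson's r recomputed per ROI, and
the maximum over ROIs retained; the FWE p is the (+1-corrected) fraction
of permutation maxima at least as large as the observed r. The family
default is signed r (the hypothesis is a positive association); a
two-sided `|r|` variant is available. The +1 correction makes the test
valid at any permutation count; under a correlated-ROI global null the
family-wise error stays at or below level (verified at 1,000 experiments
× 5,000 permutations).

# Psychophysics

The behavioural task is 2AFC foreground localization with bar luminance
adapted by a 3-down-1-up staircase on Michelson contrast
$C = (L_\mathrm{bar}-L_0)/(L_\mathrm{bar}+L_0)$. Steps are
multiplicative (0.1 log10 units before the second reversal, 0.05 after —
the staircase literature's standard schedule; the source design does not
state step sizes) and contrast is clamped to the display-feasible range
(background 43.8 cd/m², maximum bar 78.9 cd/m² → C ≤ 0.286). The
staircase converges on the 79.4% point ($0.5^{1/3}$).

`fit_weibull()` fits
$P(c) = 0.5 + (0.5 - \lambda/2)\,(1 - e^{-(c/\alpha)^\beta})$
by binomial maximum likelihood over (scale, slope) with the guess rate
fixed at 0.5 and the lapse rate fixed at $\lambda = 0.01$ (a free lapse
is unidentifiable from staircase data, which concentrates trials near
threshold). Multiple starts guard against local optima; likelihood ties
resolve to the smallest slope. The threshold is read off at the 80%
criterion and sensitivity is $S = 1/C_\mathrm{threshold}$; the
behavioural saliency sensitivity is
$SS_\mathrm{behavior} = S_{90^\circ} - S_{15^\circ}$. Validation:
averaged over simulated participants, the observer's true probability
correct at the estimated threshold is 80% ± 2 (four 60-trial staircases
per condition, as in the experimental protocol).

# Connectivity

`build_ppi_design()` implements gPPI *without deconvolution*: because
the CBV HRF is uncertain, the interaction term is the elementwise
product of the condition boxcar shifted by one paired TR (5.02 s, the
haemodynamic delay surrogate; a one-frame 2.51-s shift is available via
`shift=`) and the seed timecourse. The GLM contains the seed, the three
shifted boxcars, the three PPI terms, and per-run baseline/drift (and
optional motion) columns. Saliency-dependent connectivity is
$\Delta = \beta_{PPI,90^\circ} - \beta_{PPI,15^\circ}$, tested across
subjects with one-sample t tests and Holm correction over the two
canonical pathways (feedforward V1-superficial → IPS-middle; feedback
IPS-deep → V1-deep). Connectivity runs on the not-nulled (BOLD) stream
by default, where sensitivity is higher.

Parameter recovery uses the module's own generative model
(`simulate_coupled_target()`): target = self-coupling × seed +
condition coupling × (shifted boxcar ⊙ seed) + noise. With a
unit-variance (z-scored) seed — standard practice, making coupling betas
comparable across subjects — and the full 9-run session length, the
group estimate of a 0.3 coupling contrast is recovered within ±0.05 at
n = 20 and the uncoupled pathway stays non-significant in ≥90% of
replicates. When the target instead contains its own task activation
(as in `run_full_study()`), PPI without deconvolution acquires a
coactivation component — a known property of the method, visible there
as an inflated feedforward Δ; the pathway *asymmetry* remains the valid
readout.

# Visual-field maps and eye tracking

`reconstruct_fieldmap()` back-projects per-node responses through
isotropic Gaussian pRFs, $\sum_i \mathrm{resp}_i\,
e^{-((x-x_{0i})^2+(y-y_{0i})^2)/2\sigma_i^2}$, per cortical depth, on a
0.1° lattice over the lower visual field ([−8, 8] × [−8, 0]°); pRFs are
amplitude- (not volume-) normalized, with a flag for the alternative.
Maps are normalized by the single maximum across depths (preserving
between-depth ordering) and averaged across subjects. pRF positions are
aligned to the localizer peak by pure translation (the minimal reading
of a "linear transform"; rotation/scaling are deliberately not applied).

`preprocess_gaze()` removes ±200 ms around blinks with linear
interpolation, removes a linear trend, and subtracts per-block means;
`bcea()` quantifies fixation stability as
$2\pi k \sigma_x \sigma_y \sqrt{1-\rho^2}$ with $k = -\ln(1-P)$
($k = 2.9957$ at P = 0.95, the convention of the BCEA literature in
which $P = 1 - e^{-k}$). The Monte-Carlo containment of the 95% ellipse
is 0.95 ± 0.01 at 10⁵ Gaussian samples.

# The full study and scenario recovery

`run_full_study()` composes everything at the study's conditions
(20 subjects, 9 runs, noise 0.5%): per-subject sessions with log-normal
overall-amplitude and saliency-gain factors (the latter scales the 90°
gains and is the individual difference that survives normalization and
drives the brain–behavior correlation; behavioural sensitivities are
linked to it around the group values S₉₀ ≈ 18.7, S₁₅ ≈ 9.7, optionally
measured through full simulated staircases), preprocessing, GLM,
unmixing, normalization, ANOVAs, permutation-FWE correlation, gPPI on
the two pathways, field maps, and classification of the generative
scenario from the (V1, IPS) argmax-layer signature
(feedback → (deep, deep); V1 origin → (superficial, middle);
tecto-thalamic → (middle, middle); nearest-signature match with a
deterministic tie-break).

`scenario_recovery_experiment()` repeats cohort simulation and
classification across scenarios. For the recovery experiment the
per-subject session is scaled to 2 runs and 24 voxels per region —
*fewer* data than the study conditions, hence conservative for the
recovery claim — and classification is ≥95% correct over 100 replicates
per scenario at default noise, 100% without noise, and falls toward the
1/3 chance level when noise overwhelms the gains.

# Reproducibility, limitations, scope

Every stochastic stage takes an explicit seed; `derive_seed()` expands a
master seed counter-style, and identical seeds give bitwise-identical
simulations, permutations and reports.

What the synthetic validation does *not* show: the generator uses i.i.d.
thermal noise plus polynomial drift (no physiological or spatially
correlated noise), a 2D parametric cortex (no real mesh topology, no
partial-volume errors from segmentation), exact knowledge of the HRF
(model mismatch in real data biases laminar amplitudes), and no motion
or distortion. Passing recovery tests therefore validates the
*estimation chain*, not the acquisition-level assumptions of a real
experiment. Group statistics printed for real cohorts (specific t, F and
r values) depend on the in-house data and are out of scope; the package
validates the properties of the procedures instead.
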