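---
title: "Spectral circuit mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral circuit mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectramap)
```

## The problem and the model

Retinal bipolar cells (BCs) collect input from four spectral cone types
(red/LWS, green/RH2, blue/SWS2, UV/SWS1), directly through dendrites and
indirectly through amacrine-cell circuits. Because the cone types differ in
their spectral tuning, the *effective* cone composition of a BC's response
can be inferred from how that response varies across spectrally narrow
stimuli. `spectramap` implements this inference for calcium responses of BC
presynaptic terminals to a sequence of 13 widefield LED flashes (peaks 655
to 360 nm, 1.5 s On / 1.5 s Off, presented long-to-short).

The model is strictly linear. A terminal's trial-averaged response is
written as

$$r(t) \;=\; \sum_{c=1}^{4}\sum_{k=1}^{4} a_{ck}\, S_c(\lambda_{f(t)})\,
B_k(t - t_{f(t)}),$$

where $S_c$ is cone $c$'s spectral tuning evaluated at the flash wavelength,
$B_k$ are four flash-locked temporal components (light-transient,
light-sustained, dark-transient, dark-sustained), and the $4\times4 = 16$
coefficients $a_{ck}$ are the quantity of interest. Each cone can therefore
contribute with its own temporal signature, which is how a linear model can
absorb both dendritic and amacrine-mediated routes from the same cone.

Fitting proceeds in three steps:

1. **Temporal decomposition.** The basis $B$ is obtained by non-negative
   matrix factorization across all flash-period snippets of the responses
   and cluster means (snippets are offset by their minimum to
   non-negativity). Each trace is then projected, flash by flash, onto the
   four kernels by ordinary least squares, giving a 4 × 10 coefficient array
   over the **central 10 LEDs** (the first two red flashes and the last UV
   flash are excluded: the red end is weak and noisy, the last UV flash
   risks saturation).
2. **Spectral interpolation.** Each component's 10-point coefficient series
   is linearly interpolated onto the 360–610 nm cone wavelength grid
   (ascending wavelength, i.e. x-inverted relative to presentation order).
3. **Spectral unmixing.** Per component, the interpolated tuning is
   regressed onto the four cone tunings with a lasso penalty
   ($\|\tau_k - \sum_c w_{ck} S_c\|^2 + \lambda \|w\|_1$, no intercept),
   yielding the 16 weights.

Weights are reported in a display convention in which positive means
sign-inverting ("On"-like) and negative sign-conserving ("Off"-like); this
is the negation of the raw regression coefficient because the cone
regressors are themselves negative-going for light. Weight matrices are
also rescaled so the mean magnitude of the 16 weights is 1; weights with
|w| < 0.5 are flagged "near-zero" in summaries only — fits and
reconstructions always use all 16.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `qi_min` | 0.4 | – | inclusive quality threshold; QI < 0.4 excluded |
| `resample_rate_hz` | 42 | Hz | analysis rate after linear interpolation |
| `n_pc` | 48 | – | PCs considered before clustering |
| high-freq. PC rule | >60% power above 2 Hz | – | discards noise-dominated PCs; the source procedure states the intent but no criterion, this is our concretization |
| `k_range`, `n_init` | 1–40, 10 | – | GMM candidates and EM restarts; covariance full |
| `lasso_lambda` | `"cv"` | – | 5-fold CV over a log grid, jointly over the four components; exactness tests use 1e-6 |
| `fit_range_nm` | 407–592 | nm | span actually constrained by the central LEDs (see below) |
| opponency threshold | 0.10 (inclusive) | – | opposite-lobe amplitude relative to the dominant peak |
| group bands | 470, 510 | nm | crossing-position cut points for blue/green/UV:R/G/B groups |
| `band_hz` | 0.16–2 | Hz | band for the power-explained metric |

## The synthetic world

The generator emulates, with known ground truth, the data this analysis is
designed for:

* **Stimulus**: the 13-LED protocol above, with the measured LED peak
  wavelengths and powers.
* **Cone templates**: smooth parametric shapes — a dominant negative
  (light-evoked dip) log-wavelength bell plus an opposing lobe — with zero
  crossings solved exactly at 523 nm (green), 483 nm (blue) and 450 nm
  (UV), and a red template with no sign change that approaches zero toward
  short wavelengths. The UV opposing lobe is capped below 10% of the
  dominant peak, so a pure-UV tuning is *weakly* opponent: it crosses zero
  near 450 nm yet does not meet the 10% opponency criterion, matching the
  coexistence of a "UV-cone-like" non-opponent group with a ~450 nm
  opponent axis. Templates are sampled at the 13 LED peaks and linearly
  interpolated to the grid, emulating the format of measured cone tunings
  (which were recorded with the same stimulus).
* **Temporal kernels**: saturating-rise (sustained) and rise-times-decay
  (transient) shapes confined to the On or Off window, unit L2 norm, so all
  scale lives in the weights.
* **Population**: six weight archetypes matching the six spectral groups
  (broad, red-cone-like, UV-cone-like, green-, blue-, UV:R/G/B-opponent),
  with red-dominant totals, per-archetype temporal profiles (transient vs
  sustained), IPL depth bands (On-like UV archetypes deep, Off-like
  shallow), region biases, i.i.d. weight jitter (SD 0.1), 7 repeats
  ("typically 7 to 8"; configurable down to 3–5), repeat noise SD 0.08, and
  a slow additive ramp (0.01 units/s) plus optional exponential bleach to
  exercise detrending. The noise default was chosen so that typical
  terminals bracket the QI = 0.4 inclusion boundary — most, but not all,
  synthetic ROIs pass, as in real recordings.
* **Triplane scenes**: 128 × 64 px × 3 planes at 5.2 Hz, terminals as ~5 px
  Gaussian blobs inside a bright, weakly responsive, spontaneously active
  IPL band (the real IPL is tiled with labeled terminals), photon-like
  sqrt-intensity noise, terminal row encoding IPL depth.

What the generator does **not** emulate: optics (no PSF beyond the Gaussian
blob), motion, biosensor kinetics (no deconvolution is attempted, as in the
source procedure), eye-rotation or stimulator hardware, and spectral
adaptation. A green test therefore establishes that the *analysis* recovers
a linear world's parameters — not that real bipolar cells are linear.

Two generator properties are load-bearing and deliberate:

* Archetypes differ in their temporal component profiles. If every cell
  shared one profile the synthetic data would be temporally rank-1 and the
  NMF basis unidentifiable — real clusters differ strongly in kinetics.
* The opponent archetypes carry moderate red-cone components alongside
  their defining cone (red input dominates the inner retina). This is what
  makes the cone-shuffle randomization control destructive: shuffling
  weights across cones misaligns the red contribution and the trimodal
  zero-crossing histogram collapses. With pure single-cone archetypes the
  shuffle would merely permute template crossings among themselves.

## Numerical choices

* **QI** is `Var_t[mean_r C] / mean_r[Var_t C]`; it is 1 for identical
  repeats, tends to 1/R for i.i.d. noise, and is undefined (error) for
  all-constant input. Repeat folding assumes exact protocol periodicity
  after resampling; fractional-frame remainders are truncated, and
  synthetic scenes define an "aligned-in-time" effective frame rate with an
  integer number of samples per flash.
* **IPL detection** smooths the temporal-SD image with a Gaussian (sigma
  from a 3-px FWHM kernel; the source text self-contradictorily says
  "median-smoothing with a Gaussian kernel", so a 3×3 median filter is
  available behind `method`) and thresholds at min + 0.35 × (max − min);
  the 35% threshold is read as relative to the min–max range, flagged in
  the docs.
* **ROI placement** combines a 5-px local-mean adaptive threshold with a
  global QI floor of 0.4 (the floor prevents the weakly coherent neuropil
  from percolating into band-wide components), shrinks by city-block
  distance > 1 px to cores, and re-fills connected components.
* **NMF** uses multiplicative updates, 20 restarts keeping the lowest
  reconstruction error, fixed seed. Estimated kernels are floor-subtracted
  before unit-norming: the snippet min-shift otherwise leaves a shared DC
  offset that makes the kernel Gram matrix near-singular, and per-flash
  projections then explode into large canceling coefficient pairs.
  Kernels are labeled light/dark by On/Off-window support mass and
  transient/sustained by peak-to-plateau ratio.
* **Per-flash projection** is ordinary least squares with signed
  coefficients even though the basis came from NMF — signed weights require
  it. A Gram-matrix condition bound (1e8) guards against collinear bases.
* **Lasso** is an in-package coordinate descent (the problem is 4
  regressors; an independent package implementation serves as a test
  oracle). The regression is evaluated on the 407–592 nm sub-grid: the
  stated 360–610 nm interpolation range extends beyond the span of the
  central 10 LEDs, and the extrapolated (constant) segments would otherwise
  bias the fit — restricting the fit range makes noiseless round-trip
  recovery exact while curves are still reported on the full grid. Per
  component fitting is the default ("four cone weights × four response
  bases"); this is one of the two readings the source admits, and a joint
  fit is a one-line change on top of `lasso_cd`.
* **Opponency** is inclusive at exactly 10% of the dominant peak (dominant
  polarity = sign at the global absolute extremum); classification is
  invariant to positive rescaling. For multiple qualifying crossings, group
  assignment uses the crossing adjacent to the strongest opposite lobe.
  Non-opponent curves are assigned by absolute cosine similarity to the
  red template, UV template, or a flat broadband profile, ties broken
  toward broad.
* **GMM** uses full covariances, a small ridge (1e-6) against singularity,
  k-means initialization with multiple starts, and BIC
  (−2·loglik + p·log n) minimized over `k_range`. BIC curves flatten for
  over-parameterized worlds; the argmin is used regardless, and the exact
  cluster count is deliberately not an acceptance quantity.
* **Wilcoxon**: the source's "paired Wilcoxon Rank Sum Test" is a
  contradiction in terms; the default here is the signed-rank test on
  paired per-cluster component values, with a rank-sum option.
* **Fisher-z** confidence intervals for weight correlations (the source
  does not state its CI method).

## Known limitations

* The deposited real dataset is not bundled (no network at analysis time);
  `load_dryad_deposit()` maps a downloaded copy onto the internal types,
  and the headline real-data numbers (94.0%/5.1% variance, 103.8%/3.8%
  band power, 6,125 ROIs, 82% variance in 48 PCs) are therefore reachable
  but not asserted by the test suite.
* Desk-scale populations (~10² ROIs) do not support 29 clusters; BIC merges
  archetypes when per-cluster membership cannot sustain a full covariance.
  The cluster-recovery guarantees hold in the separable regime the tests
  construct.
* The exact morphological "shrink" used for ROI placement and the exact
  six-group assignment rule are under-specified at the source; both are
  parameterized here (`core_dist`, `bands`) and our defaults reproduce the
  stated group crossing ranges without guaranteeing an identical partition.
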