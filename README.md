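# spectramap

Spectral circuit mapping of cone inputs to retinal bipolar cells.

`spectramap` infers the effective cone-photoreceptor inputs to bipolar-cell
(BC) presynaptic terminals from in vivo two-photon calcium responses to a
sequence of 13 spectrally narrow full-field flashes (LED peaks 655 → 360 nm,
1.5 s On / 1.5 s Off). It is written for researchers analyzing spectral
tuning in the inner retina — and for anyone who wants a fully synthetic,
ground-truth-controlled replica of that analysis.

At its core is a linear model: each trial-averaged terminal response is

    r(t) = sum_c sum_k  a[c,k] * S_c(lambda_flash) * B_k(t - t_flash)

with four cone spectral tunings `S_c` (red, green, blue, UV; zero crossings
near 523, 483 and 450 nm for green, blue and UV) and four flash-locked
temporal components `B_k` (light-transient, light-sustained, dark-transient,
dark-sustained, obtained by NMF), giving 4 × 4 = 16 weights per cell. The
weights are estimated by per-flash least-squares projection onto the
temporal basis (a 4 × 10 array over the central 10 LEDs), linear
interpolation onto the 360–610 nm cone grid, and lasso regression onto the
cone tunings. Downstream analyses classify spectral opponency (inclusive
10%-of-peak overshoot criterion), zero crossings, and six spectral groups,
and quantify reconstruction quality by across-cluster variance and
band-limited (0.16–2 Hz) power.

The package contains six modules:

* synthetic data — stimulus protocols, cone templates, temporal kernels,
  ground-truth weight populations, trial-resolved traces and triplane
  image stacks (`make_stimulus_protocol`, `make_cone_tunings`,
  `make_temporal_basis`, `make_population`, `simulate_roi_traces`,
  `simulate_triplane_stack`);
* preprocessing — detrending/resampling to 42 Hz, z-scoring, a
  repeat-coherence quality index (QI; ROIs with QI < 0.4 excluded), IPL
  detection, per-pixel QI images and ROI placement (`compute_qi`,
  `detect_ipl`, `qi_image`, `place_rois`, `extract_rois_from_scene`);
* clustering — PCA (48 PCs, high-frequency PCs discarded) plus
  full-covariance Gaussian mixtures selected by BIC (`pca_reduce`,
  `fit_gmm_bic`, `summarize_clusters`);
* decomposition — NMF temporal basis, flash decomposition, lasso cone
  weights, normalization (mean |w| = 1) and reconstruction
  (`extract_temporal_basis_nmf`, `decompose_response`, `fit_cone_weights`,
  `reconstruct`);
* tuning analysis — bulk tunings, crossings, opponency, spectral groups,
  crossing histograms with randomization controls, weight statistics,
  correlations and weight-by-IPL-depth histograms;
* orchestration — `run_pipeline()` with a JSON config/manifest and a
  mapping-driven adapter (`load_dryad_deposit`) for the deposited per-ROI
  dataset.

## Worked example

```r
library(spectramap)

cfg <- pipeline_config(seed = 1, n_rois = 150, k_range = 1:8, n_init = 4,
                       outdir = "demo_run")
run_pipeline(cfg)

metrics <- jsonlite::read_json("demo_run/metrics.json",
                               simplifyVector = TRUE)
round(metrics$variance_explained_pct, 1)
#> [1] 93.5
round(metrics$residual_variance_pct, 1)
#> [1] 6.9
round(metrics$power_explained_pct, 1)
#> [1] 99
round(metrics$residual_power_pct, 1)
#> [1] 1.7
table(read.csv("demo_run/groups.csv")$group)
#>
#>           broad  green_opponent   red_cone_like uv_rgb_opponent
#>               1               1               1               5
```

What this says: 150 synthetic terminals were generated from six
ground-truth spectral archetypes, 84 passed the QI ≥ 0.4 quality filter,
BIC selected 8 functional clusters, and the 16-weight linear cone model
reconstructed the cluster means almost completely — 93.5% of the
across-cluster variance (6.9% left in the residuals) and 99% of the
band-limited temporal power (1.7% residual). The fitted clusters fall into
the expected spectral groups; at this desk scale the blue-opponent and
UV-cone-like archetypes sit near the 10%-opponency boundary and merge with
their neighbors, which is discussed in the methods vignette
(`vignettes/spectral-circuit-mapping.Rmd`).

Single-object entry points mirror the pipeline, e.g.:

```r
protocol <- make_stimulus_protocol()
cones <- make_cone_tunings()
basis <- make_temporal_basis(protocol)
fit <- decompose_to_weights(trace, basis, protocol, cones,
                            lasso_lambda = 1e-6)
fit$w_norm          # 4 cones x 4 components, mean |w| = 1
bulk_tuning(fit, cones)
```

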