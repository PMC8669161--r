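Package: spectramap
Title: Spectral Circuit Mapping of Cone Inputs to Retinal Bipolar Cells
Version: 0.1.0
Authors@R:
    person("Spectramap", "Developers", email = "spectramap@example.org",
           role = c("aut", "cre"))
Description: Infers the effective cone-photoreceptor inputs to retinal bipolar
    cell terminals from in vivo calcium responses to a series of spectrally
    narrow light flashes. Provides a ground-truth synthetic data generator
    (stimulus protocols, cone spectral templates, flash-locked temporal
    kernels, trial-resolved traces and triplane image stacks), preprocessing
    (detrending, z-scoring, a repeat-coherence quality index, inner plexiform
    layer detection and ROI placement), PCA plus Gaussian-mixture clustering
    with BIC model selection, decomposition of responses into four temporal
    components per flash followed by lasso regression onto four cone spectral
    tunings (16 weights per cell), and downstream spectral tuning analysis
    (zero crossings, opponency classification, six spectral groups,
    reconstruction-quality metrics, weight statistics and randomization
    controls).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
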