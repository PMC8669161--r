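# shared fixtures, built in code (cached per test run)

default_protocol <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_stimulus_protocol()
    val
  }
})

default_cones <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_cone_tunings()
    val
  }
})

default_basis <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_temporal_basis(make_stimulus_protocol())
    val
  }
})

# noiseless single-repeat signal for a weight matrix (display convention)
forward_trace <- function(W, protocol = default_protocol(),
                          cones = default_cones(),
                          basis = default_basis()) {
  S <- spectramap:::eval_cone_tunings(cones, protocol$led_peaks_nm)
  spectramap:::forward_signal(W, S, basis$kernels)
}

# sample indices of the central-flash window of a full-stimulus trace
central_window <- function(protocol = default_protocol(),
                           rate = protocol$resample_rate_hz) {
  P <- spectramap:::samples_per_flash(protocol, rate)
  as.vector(vapply(protocol$central_led_indices,
                   function(f) ((f - 1) * P + 1):(f * P), integer(P)))
}

rand_weights <- function(lo = -2, hi = 2) {
  matrix(stats::runif(16, lo, hi), 4, 4,
         dimnames = list(c("red", "green", "blue", "uv"),
                         c("Ltr", "Lsus", "Dtr", "Dsus")))
}

# small well-separated population for cluster/decompose pipelines
small_population <- function(n = 120, noise_sd = 0.05, seed = 42,
                             n_repeats = 5) {
  make_population(n_rois = n, noise_sd = noise_sd, n_repeats = n_repeats,
                  weight_jitter = 0.05, seed = seed)
}
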