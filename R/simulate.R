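# Forward model: traces and triplane stacks -----------------------------------

# Weight sign convention: stored weights follow the display convention
# (positive = sign-inverting "On" input, negative = sign-conserving "Off").
# The forward/regression coefficient on the signed cone tunings is the
# negation of that convention; these helpers keep the two in one place.
weights_to_raw <- function(w) -w
raw_to_weights <- function(a) -a

# noiseless single-repeat signal (all flashes) for one weight matrix, given
# the cone tunings sampled at the LED peaks (S: n_leds x 4) and the kernel
# matrix B (P x 4)
forward_signal <- function(w, S, B) {
  a <- weights_to_raw(w)                    # 4 cones x 4 components
  amp <- t(S %*% a)                         # components x leds
  as.vector(B %*% amp)                      # P x n_leds, column-stacked
}

#' Simulate trial-resolved traces for a ground-truth population
#'
#' Forward model: for every repeat, the trace is the sum over cones c and
#' temporal components k of `w[c,k] * S_c(lambda_flash) * B_k(t - t_flash)`
#' (in raw regression sign; stored weights use the display convention, see
#' package docs), plus optional slow drift (linear ramp and exponential
#' bleach) and i.i.d. Gaussian repeat noise. A pre-stimulus baseline segment
#' (noise + drift only) is generated for z-scoring.
#'
#' @param population a `bc_population`.
#' @param protocol a `stim_protocol`.
#' @param cones a `cone_tunings` set; evaluated at the LED peaks (constant
#'   extrapolation outside the grid).
#' @param basis a `temporal_basis` sampled at `rate`.
#' @param rate sampling rate (Hz); must match the basis.
#' @param seed RNG seed (default: the population's seed + 1).
#' @return List of `roi_record` objects, each with elements `id`, `baseline`
#'   (pre-stimulus samples), `repeats` (T x R matrix), `ipl_depth`, `region`,
#'   and `truth` (weights, noiseless signal, archetype).
#' @export
simulate_roi_traces <- function(population, protocol, cones, basis,
                                rate = protocol$resample_rate_hz,
                                seed = population$seed + 1L) {
  if (abs(basis$rate_hz - rate) > 1e-9)
    stop("dimension error: basis sampling rate does not match trace rate")
  P <- samples_per_flash(protocol, rate)
  if (nrow(basis$kernels) != P)
    stop("dimension error: basis length does not match protocol flash period")
  set.seed(seed)
  S <- eval_cone_tunings(cones, protocol$led_peaks_nm)
  B <- basis$kernels
  T_rep <- P * protocol$n_leds
  n_base <- as.integer(round(protocol$baseline_s * rate))
  R <- population$n_repeats
  t_all <- (seq_len(n_base + T_rep * R) - 1) / rate
  lapply(seq_len(population$n_rois), function(i) {
    sig <- forward_signal(population$weights[[i]], S, B)
    drift <- population$drift_ramp * t_all
    if (population$bleach_amp > 0)
      drift <- drift + population$bleach_amp * exp(-t_all /
                                                     population$bleach_tau)
    noise <- stats::rnorm(length(t_all), 0, population$noise_sd)
    full <- rep(c(rep(0, n_base), rep(sig, R))[seq_along(t_all)], 1) +
      drift + noise
    structure(list(
      id = i,
      baseline = full[seq_len(n_base)],
      repeats = matrix(full[-seq_len(n_base)], nrow = T_rep, ncol = R),
      ipl_depth = population$ipl_depth[i],
      region = as.character(population$region[i]),
      truth = list(weights = population$weights[[i]],
                   signal = sig,
                   archetype = as.character(population$archetype[i]))
    ), class = "roi_record")
  })
}

#' Simulate a triplane fluorescence stack with ground truth
#'
#' Renders a population of bipolar-cell terminals as isotropic Gaussian blobs
#' (~5 px diameter) inside an IPL band on each imaging plane, with each
#' blob's time course driven by the forward model at the native acquisition
#' rate, on a dim background with photon-like noise. Terminal rows encode IPL
#' depth (top border = inner-nuclear-layer side).
#'
#' @param population a `bc_population` (terminal count = `n_rois`).
#' @param protocol a `stim_protocol`.
#' @param cones,basis cone tunings and a temporal basis at the native rate
#'   (`basis` defaults to [make_temporal_basis()] at `frame_rate_hz`).
#' @param geometry list with `nx`, `ny` (pixels per plane), `n_planes`,
#'   `pixel_size_um`, `band` (IPL band rows, `c(top, bottom)`), `min_sep_px`
#'   (minimal terminal separation).
#' @param blob_sigma_px Gaussian radius of a terminal (sigma; default gives
#'   ~5 px diameter).
#' @param baseline_F background fluorescence outside the IPL (counts).
#' @param band_baseline_F baseline fluorescence inside the IPL band: the
#'   band is filled with labeled terminals and hence brighter.
#' @param band_noise SD of additional incoherent fluctuation inside the band
#'   (spontaneous activity: raises the temporal SD used for IPL detection
#'   without adding repeat coherence).
#' @param neuropil_gain counts per unit of the weak coherent neuropil
#'   signal (population-mean response) added across the band.
#' @param gain fluorescence counts per trace unit at a terminal center.
#' @param photon_noise scale of the sqrt-intensity Gaussian noise.
#' @param seed RNG seed.
#' @return An object of class `synthetic_scene`: list with `stack` (time x
#'   y x x x plane array), `terminal_centers` (data.frame x/y/plane/id),
#'   `ipl_band`, `pixel_size_um`, `protocol`, `n_repeats`, plus the noiseless
#'   per-terminal traces in `truth`.
#' @export
simulate_triplane_stack <- function(population, protocol, cones,
                                    basis = make_temporal_basis(
                                      protocol, rate = protocol$frame_rate_hz),
                                    geometry = list(nx = 128, ny = 64,
                                                    n_planes = 3,
                                                    pixel_size_um = 0.26,
                                                    band = c(14, 50),
                                                    min_sep_px = 8),
                                    blob_sigma_px = 1.1,
                                    baseline_F = 15, band_baseline_F = 60,
                                    band_noise = 4, neuropil_gain = 8,
                                    gain = 80, photon_noise = 0.5,
                                    seed = population$seed + 2L) {
  set.seed(seed)
  nx <- geometry$nx; ny <- geometry$ny; np <- geometry$n_planes
  band <- geometry$band
  P <- samples_per_flash(protocol, protocol$frame_rate_hz)
  # effective ("aligned-in-time") rate: exactly P samples per flash period,
  # so folding into repeats stays exact after resampling
  rate <- P / protocol$period_s
  if (nrow(basis$kernels) != P)
    stop("dimension error: basis must be sampled at the native frame rate")
  n_term <- population$n_rois
  R <- population$n_repeats
  n_base <- as.integer(round(protocol$baseline_s * rate))
  T_rep <- P * protocol$n_leds
  T_tot <- n_base + T_rep * R

  # place terminals inside the IPL band, rows encoding depth; reject overlaps
  margin <- 4
  centers <- data.frame(x = numeric(0), y = numeric(0), plane = integer(0))
  max_tries <- 200 * n_term
  per_plane <- rep(seq_len(np), length.out = n_term)
  tries <- 0
  for (i in seq_len(n_term)) {
    pl <- per_plane[i]
    row_i <- band[1] + population$ipl_depth[i] * (band[2] - band[1])
    repeat {
      tries <- tries + 1
      if (tries > max_tries)
        stop("placement error: geometry too small for requested terminals")
      cx <- stats::runif(1, margin, nx - margin)
      same <- centers[centers$plane == pl, , drop = FALSE]
      if (nrow(same) == 0 ||
          min(sqrt((same$x - cx)^2 + (same$y - row_i)^2)) >=
            geometry$min_sep_px) break
    }
    centers <- rbind(centers, data.frame(x = cx, y = row_i, plane = pl))
  }
  centers$id <- seq_len(n_term)

  S <- eval_cone_tunings(cones, protocol$led_peaks_nm)
  B <- basis$kernels
  stack <- array(baseline_F, dim = c(T_tot, ny, nx, np))
  band_rows <- band[1]:band[2]
  truth_traces <- matrix(0, T_rep, n_term)
  sigs <- vapply(population$weights, forward_signal, numeric(P *
                                                              protocol$n_leds),
                 S = S, B = B)
  truth_traces[] <- sigs
  # IPL band: brighter, weakly responsive neuropil with incoherent activity
  np_sig <- c(rep(0, n_base), rep(rowMeans(sigs), R))
  n_band_px <- length(band_rows) * nx
  for (pl in seq_len(np)) {
    bandvals <- (band_baseline_F - baseline_F) + neuropil_gain * np_sig +
      matrix(stats::rnorm(T_tot * n_band_px, 0, band_noise), T_tot)
    dim(bandvals) <- c(T_tot, length(band_rows), nx)
    stack[, band_rows, , pl] <- stack[, band_rows, , pl] + bandvals
  }
  half <- 3L  # footprint half-width in px
  for (i in seq_len(n_term)) {
    sig <- sigs[, i]
    tc <- baseline_F + gain * c(rep(0, n_base), rep(sig, R))
    rows <- max(1, round(centers$y[i]) - half):min(ny, round(centers$y[i]) + half)
    cols <- max(1, round(centers$x[i]) - half):min(nx, round(centers$x[i]) + half)
    fp <- outer(exp(-0.5 * ((rows - centers$y[i]) / blob_sigma_px)^2),
                exp(-0.5 * ((cols - centers$x[i]) / blob_sigma_px)^2))
    # add (tc - baseline_F) so overlapping footprints sum over background
    add <- outer(tc - baseline_F, fp)
    dim(add) <- c(T_tot, length(rows), length(cols))
    stack[, rows, cols, centers$plane[i]] <-
      stack[, rows, cols, centers$plane[i]] + add
  }
  if (photon_noise > 0)
    stack <- stack + stats::rnorm(length(stack)) * photon_noise *
      sqrt(pmax(stack, 1))
  structure(list(
    stack = stack,
    terminal_centers = centers,
    ipl_band = band,
    pixel_size_um = geometry$pixel_size_um,
    protocol = protocol,
    n_repeats = R,
    n_baseline_samples = n_base,
    rate_hz = rate,
    truth = list(traces = truth_traces, population = population)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$stack)
  cat("Synthetic triplane scene:", d[1], "frames,", d[2], "x", d[3],
      "px,", d[4], "planes,", nrow(x$terminal_centers), "terminals\n")
  invisible(x)
}
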