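# Decomposition into temporal components and cone weights ---------------------

# cut a full-stimulus trace into a samples-per-flash x n_leds matrix
flash_snippets <- function(trace, protocol, rate) {
  P <- samples_per_flash(protocol, rate)
  need <- P * protocol$n_leds
  if (length(trace) < need)
    stop("trace does not cover all flashes")
  matrix(trace[seq_len(need)], nrow = P, ncol = protocol$n_leds)
}

#' Decompose a trial-averaged trace into per-flash temporal coefficients
#'
#' For each of the protocol's central LEDs, the flash-period snippet of the
#' trace is projected (ordinary least squares, signed coefficients) onto the
#' four temporal kernels, yielding a 4 x 10 array (temporal components x
#' central LEDs).
#'
#' @param trace_mean trial-averaged trace covering all flashes (baseline
#'   removed) at `rate`.
#' @param basis a `temporal_basis` at the same rate.
#' @param protocol a `stim_protocol`.
#' @param rate sampling rate (Hz).
#' @param max_kappa conditioning bound on the kernel Gram matrix.
#' @return An object of class `flash_decomposition`: `coeffs` (4 x 10 matrix,
#'   rows Ltr/Lsus/Dtr/Dsus, columns named by LED peak nm), `led_subset`,
#'   `component_order`.
#' @export
decompose_response <- function(trace_mean, basis, protocol,
                               rate = protocol$resample_rate_hz,
                               max_kappa = 1e8) {
  B <- basis$kernels
  P <- samples_per_flash(protocol, rate)
  if (nrow(B) != P)
    stop("dimension error: basis length does not match flash period")
  G <- crossprod(B)
  if (kappa(G) > max_kappa)
    stop("conditioning error: temporal kernels are near-collinear")
  snips <- flash_snippets(trace_mean, protocol, rate)
  idx <- protocol$central_led_indices
  coeffs <- solve(G, crossprod(B, snips[, idx, drop = FALSE]))
  dimnames(coeffs) <- list(colnames(B), protocol$led_peaks_nm[idx])
  structure(list(coeffs = coeffs,
                 led_subset = protocol$led_peaks_nm[idx],
                 component_order = colnames(B)),
            class = "flash_decomposition")
}

#' Interpolate per-LED coefficients onto the cone wavelength grid
#'
#' Linear interpolation between LED peak wavelengths, constant extrapolation
#' at the grid edges. The output is on an ascending wavelength axis
#' (x-inverted relative to the long-to-short presentation order, following
#' the convention of plotting spectral tunings from short to long
#' wavelengths).
#'
#' @param coeff_row numeric values, one per LED (any order).
#' @param led_peaks corresponding LED peak wavelengths (nm).
#' @param grid target wavelength grid (nm), default 360:610.
#' @return Numeric vector on `grid`.
#' @export
interpolate_tuning <- function(coeff_row, led_peaks, grid = 360:610) {
  stopifnot(length(coeff_row) == length(led_peaks), length(led_peaks) >= 2)
  o <- order(led_peaks)
  stats::approx(led_peaks[o], coeff_row[o], xout = grid, rule = 2)$y
}

#' Fit cone weights to component tuning curves by lasso regression
#'
#' For each temporal component k, solves
#' `argmin_w ||tau_k - sum_c w[c,k] S_c||^2 + lambda ||w||_1` (no intercept)
#' over the four cone spectral tunings `S_c`, giving the 4 cones x 4
#' components weight matrix. The returned weights follow the display sign
#' convention (positive = sign-inverting "On" input), i.e. the regression
#' coefficients are negated; both unnormalized and normalized (mean |w| = 1)
#' copies are returned.
#'
#' @param tunings matrix (wavelengths x 4 components) of interpolated
#'   component tuning curves, on the cone grid.
#' @param cone_set a `cone_tunings` object on the same grid.
#' @param lasso_lambda penalty; a number, or `"cv"` for 5-fold
#'   cross-validation over a log-spaced grid (jointly over the four
#'   components).
#' @param fit_range_nm wavelength range over which the regression is
#'   evaluated, default `c(407, 592)`: the span actually constrained by the
#'   central LEDs. Outside it the interpolated component tunings are pure
#'   extrapolation and would bias the fit. Use `NULL` for the full grid.
#' @return An object of class `cone_weights`: `w` (unnormalized 4x4, rows
#'   red/green/blue/uv, columns Ltr/Lsus/Dtr/Dsus), `w_norm` (mean |w| = 1;
#'   equal to `w` with a flag if all weights are zero), `lambda`,
#'   `near_zero_threshold` (0.5, display/summary only).
#' @export
fit_cone_weights <- function(tunings, cone_set, lasso_lambda = "cv",
                             fit_range_nm = c(407, 592)) {
  tunings <- as.matrix(tunings)
  S <- cone_set$tuning
  if (nrow(tunings) != nrow(S))
    stop("dimension error: tunings and cone set must share the grid")
  if (!is.null(fit_range_nm)) {
    sel <- cone_set$wavelength_nm >= fit_range_nm[1] &
      cone_set$wavelength_nm <= fit_range_nm[2]
    if (sum(sel) < ncol(S)) stop("fit_range_nm leaves too few grid points")
    S <- S[sel, , drop = FALSE]
    tunings <- tunings[sel, , drop = FALSE]
  }
  if (qr(S)$rank < ncol(S))
    stop("conditioning error: degenerate cone set (rank < 4)")
  lambda <- if (identical(lasso_lambda, "cv"))
    cv_lasso_lambda(S, tunings) else as.numeric(lasso_lambda)
  a <- vapply(seq_len(ncol(tunings)), function(k)
    lasso_cd(S, tunings[, k], lambda), numeric(ncol(S)))
  a <- matrix(a, ncol(S), ncol(tunings))
  w <- raw_to_weights(a)
  dimnames(w) <- list(colnames(S),
                      colnames(tunings) %||% c("Ltr", "Lsus", "Dtr", "Dsus"))
  all_zero <- all(w == 0)
  structure(list(w = w,
                 w_norm = if (all_zero) w else normalize_weights(w),
                 all_zero = all_zero,
                 lambda = lambda,
                 near_zero_threshold = 0.5),
            class = "cone_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale a weight matrix so the mean magnitude equals one
#'
#' @param W numeric weight matrix (or `cone_weights`), not all zero.
#' @return `W / mean(|W|)`; signs preserved.
#' @export
normalize_weights <- function(W) {
  if (inherits(W, "cone_weights")) W <- W$w
  m <- mean(abs(W))
  if (m == 0) stop("cannot normalize an all-zero weight matrix")
  W / m
}

#' @export
print.cone_weights <- function(x, ...) {
  cat("Cone x temporal-component weights (positive = sign-inverting 'On'):\n")
  print(round(x$w_norm, 2))
  cat("lambda =", format(x$lambda), "; mean |w| of normalized copy =",
      round(mean(abs(x$w_norm)), 3), "\n")
  invisible(x)
}

#' Reconstruct a response from cone weights
#'
#' Builds the modeled trace over the central flashes as the sum of the 16
#' cone x component sub-traces `w[c,k] * S_c(lambda_f) * B_k(t)` (weights in
#' display convention; the regression sign is restored internally), and
#' returns the full reconstruction together with per-cone totals and the 16
#' sub-traces. Reconstructions always use all 16 weights; the near-zero rule
#' only ever affects summaries.
#'
#' @param W `cone_weights` or an (unnormalized) 4x4 weight matrix in display
#'   convention.
#' @param cone_set a `cone_tunings`.
#' @param basis a `temporal_basis`.
#' @param protocol a `stim_protocol`.
#' @param rate sampling rate (Hz).
#' @return List with `full` (vector over 10 central flash periods),
#'   `per_cone` (4 x T matrix), `sub` (4 cones x 4 components x T array),
#'   `led_subset`.
#' @export
reconstruct <- function(W, cone_set, basis, protocol,
                        rate = protocol$resample_rate_hz) {
  if (inherits(W, "cone_weights")) W <- W$w
  a <- weights_to_raw(W)
  idx <- protocol$central_led_indices
  S <- eval_cone_tunings(cone_set, protocol$led_peaks_nm[idx])
  B <- basis$kernels
  P <- nrow(B)
  T_ <- P * length(idx)
  sub <- array(0, c(4, 4, T_),
               dimnames = list(rownames(W), colnames(W), NULL))
  for (ci in seq_len(4)) for (k in seq_len(4)) {
    amp <- a[ci, k] * S[, ci]                 # per central flash
    sub[ci, k, ] <- as.vector(B[, k] %o% amp)
  }
  per_cone <- apply(sub, c(1, 3), sum)
  list(full = colSums(per_cone), per_cone = per_cone, sub = sub,
       led_subset = protocol$led_peaks_nm[idx])
}

#' One-call decomposition of a trace into cone weights
#'
#' Convenience wrapper: [decompose_response()], [interpolate_tuning()] per
#' component, then [fit_cone_weights()].
#'
#' @inheritParams decompose_response
#' @inheritParams fit_cone_weights
#' @return A `cone_weights` object with the `flash_decomposition` attached as
#'   attribute `"decomposition"`.
#' @export
decompose_to_weights <- function(trace_mean, basis, protocol, cone_set,
                                 lasso_lambda = "cv",
                                 fit_range_nm = c(407, 592),
                                 rate = protocol$resample_rate_hz) {
  dec <- decompose_response(trace_mean, basis, protocol, rate)
  tun <- vapply(seq_len(nrow(dec$coeffs)), function(k)
    interpolate_tuning(dec$coeffs[k, ], dec$led_subset,
                       grid = cone_set$wavelength_nm),
    numeric(length(cone_set$wavelength_nm)))
  colnames(tun) <- rownames(dec$coeffs)
  out <- fit_cone_weights(tun, cone_set, lasso_lambda, fit_range_nm)
  attr(out, "decomposition") <- dec
  out
}
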