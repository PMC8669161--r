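# Trace preprocessing ----------------------------------------------------------

#' Linearly detrend and resample a trace
#'
#' Removes the best-fit line and linearly interpolates the result onto a
#' regular grid at `target_rate`. Output length is `ceiling(duration *
#' target_rate)` with `duration = length(trace) / native_rate`.
#'
#' @param trace numeric vector.
#' @param native_rate original sampling rate (Hz), > 0.
#' @param target_rate analysis rate (Hz), default 42.
#' @return Resampled, detrended numeric vector.
#' @export
detrend_and_resample <- function(trace, native_rate, target_rate = 42) {
  if (length(trace) < 2) stop("trace shorter than 2 samples")
  stopifnot(native_rate > 0, target_rate > 0)
  tt <- (seq_along(trace) - 1) / native_rate
  fit <- stats::lm.fit(cbind(1, tt), trace)
  resid <- fit$residuals
  duration <- length(trace) / native_rate
  t_new <- (seq_len(ceiling(duration * target_rate)) - 1) / target_rate
  stats::approx(tt, resid, xout = t_new, rule = 2)$y
}

#' Repeat-coherence quality index
#'
#' `QI = Var_t[mean_r C] / mean_r[Var_t C]` for a T x R response matrix
#' (time samples x stimulus repetitions): the ratio of variance shared
#' between stimulus repetitions to the variance within single repetitions.
#' 1 means all repetitions are identical; for pure i.i.d. noise the
#' expectation approaches 1/R.
#'
#' @param C numeric matrix, time samples x repeats (R >= 2).
#' @return Scalar QI in \[0, 1\] (up to floating error).
#' @examples
#' x <- sin(seq(0, 6 * pi, length.out = 200))
#' compute_qi(cbind(x, x, x))  # 1
#' @export
compute_qi <- function(C) {
  C <- as.matrix(C)
  if (ncol(C) < 2) stop("QI needs at least 2 repeats")
  if (any(!is.finite(C))) stop("QI needs finite entries")
  within <- mean(apply(C, 2, stats::var))
  if (within == 0) stop("undefined QI: all repeats are constant (0/0)")
  stats::var(rowMeans(C)) / within
}

#' Z-score a trace against a pre-stimulus baseline
#'
#' @param trace numeric vector (the part to be z-scored).
#' @param baseline numeric vector of baseline samples; alternatively give
#'   `baseline_n` to use the first `baseline_n` samples of `trace` as
#'   baseline (they remain part of the output).
#' @param baseline_n optional count of leading baseline samples.
#' @return `(trace - mean(baseline)) / sd(baseline)`.
#' @export
zscore_trace <- function(trace, baseline = NULL, baseline_n = NULL) {
  if (is.null(baseline)) {
    if (is.null(baseline_n)) stop("give baseline samples or baseline_n")
    if (baseline_n < 2 || baseline_n > length(trace))
      stop("invalid baseline window")
    baseline <- trace[seq_len(baseline_n)]
  }
  s <- stats::sd(baseline)
  if (!is.finite(s) || s == 0) stop("zero baseline SD: cannot z-score")
  (trace - mean(baseline)) / s
}

#' Filter ROIs by quality index
#'
#' Keeps ROIs with `qi >= qi_min`; strictly smaller values are excluded
#' (exclusion criterion is QI < 0.4).
#'
#' @param rois list of `roi_record`s (with `$qi`) or a data.frame with a
#'   `qi` column.
#' @param qi_min inclusive threshold, default 0.4.
#' @return The kept subset, same container type as the input.
#' @export
filter_rois <- function(rois, qi_min = 0.4) {
  if (is.data.frame(rois)) return(rois[rois$qi >= qi_min, , drop = FALSE])
  rois[vapply(rois, function(r) isTRUE(r$qi >= qi_min), logical(1))]
}

# fold a long vector into a time x repeats matrix, truncating any fractional
# remainder (protocol periodicity is assumed exact after resampling)
fold_repeats <- function(x, samples_per_rep) {
  R <- length(x) %/% samples_per_rep
  if (R < 2) stop("fewer than 2 repeats identifiable")
  matrix(x[seq_len(samples_per_rep * R)], nrow = samples_per_rep, ncol = R)
}

# full per-record preprocessing used by the pipeline: linearly detrend the
# whole recording, z-score against the baseline segment, average repeats,
# compute QI
preprocess_record <- function(rec) {
  n_base <- length(rec$baseline)
  full <- c(rec$baseline, as.vector(rec$repeats))
  tt <- seq_along(full)
  fit <- stats::lm.fit(cbind(1, tt), full)
  full <- fit$residuals
  z_base <- full[seq_len(n_base)]
  s <- stats::sd(z_base)
  if (!is.finite(s) || s == 0) stop("zero baseline SD in record ", rec$id)
  z <- matrix((full[-seq_len(n_base)] - mean(z_base)) / s,
              nrow = nrow(rec$repeats), ncol = ncol(rec$repeats))
  rec$trace_repeats <- z
  rec$trace_mean <- rowMeans(z)
  rec$qi <- compute_qi(z)
  rec
}
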