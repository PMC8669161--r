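# Canonical flash-locked temporal kernels -------------------------------------

#' Construct the canonical four-kernel temporal basis
#'
#' Builds the four flash-locked temporal components used by the linear model:
#' light-transient (Ltr), light-sustained (Lsus), dark-transient (Dtr) and
#' dark-sustained (Dsus), sampled over one flash period (On + Off) at the
#' protocol's analysis rate. Transient kernels rise fast and decay; sustained
#' kernels rise to a plateau. All kernels are non-negative and unit L2 norm,
#' so all response scale lives in the weights.
#'
#' @param protocol a `stim_protocol`.
#' @param rate sampling rate in Hz (default: the protocol's analysis rate).
#' @param tau_rise rise time constant (s).
#' @param tau_decay transient decay time constant (s).
#' @param tau_sus sustained rise time constant (s).
#' @return An object of class `temporal_basis`: list with `kernels`
#'   (samples x 4 matrix, columns Ltr/Lsus/Dtr/Dsus), `rate_hz`, `on_s`,
#'   `off_s`, `time_s`.
#' @examples
#' b <- make_temporal_basis(make_stimulus_protocol())
#' colSums(b$kernels^2)  # all 1
#' @export
make_temporal_basis <- function(protocol, rate = protocol$resample_rate_hz,
                                tau_rise = 0.05, tau_decay = 0.25,
                                tau_sus = 0.15) {
  P <- samples_per_flash(protocol, rate)
  tt <- (seq_len(P) - 1) / rate
  on <- tt < protocol$on_s
  shape_tr <- function(t) (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  shape_sus <- function(t) (1 - exp(-t / tau_sus))
  k <- matrix(0, P, 4, dimnames = list(NULL, c("Ltr", "Lsus", "Dtr", "Dsus")))
  k[on, "Ltr"] <- shape_tr(tt[on])
  k[on, "Lsus"] <- shape_sus(tt[on])
  k[!on, "Dtr"] <- shape_tr(tt[!on] - protocol$on_s)
  k[!on, "Dsus"] <- shape_sus(tt[!on] - protocol$on_s)
  k <- sweep(k, 2, sqrt(colSums(k^2)), "/")
  structure(list(kernels = k, rate_hz = rate, on_s = protocol$on_s,
                 off_s = protocol$off_s, time_s = tt),
            class = "temporal_basis")
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat("Temporal basis:", ncol(x$kernels), "kernels (",
      paste(colnames(x$kernels), collapse = ", "), ") over ",
      nrow(x$kernels), " samples at ", x$rate_hz, " Hz\n", sep = "")
  invisible(x)
}
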