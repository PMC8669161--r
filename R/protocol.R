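# Stimulus protocol -----------------------------------------------------------

#' Construct a spectral flash stimulus protocol
#'
#' Describes a sequence of full-field flashes from spectrally narrow LEDs,
#' presented in order from long to short wavelengths, each flash consisting of
#' an On period followed by an Off (dark) period. Defaults reproduce the
#' 13-LED protocol used throughout the package: peaks from 655 nm down to
#' 360 nm, 1.5 s On / 1.5 s Off, acquired at 5.2 Hz and analysed at 42 Hz.
#'
#' The "central" LEDs are the subset used for model fitting: the first two
#' (longest-wavelength) flashes and the last (shortest-wavelength, UV) flash
#' are excluded, leaving 10 of 13 LEDs.
#'
#' @param led_peaks_nm LED peak wavelengths in nm, strictly decreasing
#'   (presentation order, long to short).
#' @param led_powers_uW maximal LED power output in microwatts, one per LED.
#' @param on_s,off_s flash On and Off durations in seconds.
#' @param frame_rate_hz native acquisition rate (Hz).
#' @param resample_rate_hz analysis sampling rate after interpolation (Hz).
#' @param baseline_s pre-stimulus baseline duration in seconds (used for
#'   z-scoring).
#' @param central_led_indices integer indices (1-based) of the LEDs used for
#'   reconstruction. Default: all but the first two and the last.
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- make_stimulus_protocol()
#' p$n_leds              # 13
#' p$led_peaks_nm[p$central_led_indices]  # the central 10 LEDs
#' @export
make_stimulus_protocol <- function(
    led_peaks_nm = c(655, 635, 622, 592, 550, 516, 501, 464, 448, 427, 407,
                     381, 360),
    led_powers_uW = c(1.31, 1.06, 0.96, 0.62, 1.26, 3.43, 1.47, 0.44, 3.67,
                      0.91, 0.24, 0.23, 0.20),
    on_s = 1.5, off_s = 1.5,
    frame_rate_hz = 5.2, resample_rate_hz = 42,
    baseline_s = 5,
    central_led_indices = NULL) {
  n <- length(led_peaks_nm)
  if (n < 2L) stop("invalid protocol: need at least two LEDs")
  if (any(diff(led_peaks_nm) >= 0))
    stop("invalid protocol: LED peaks must be strictly decreasing ",
         "(presentation order long to short)")
  if (length(led_powers_uW) != n)
    stop("invalid protocol: one power value per LED required")
  if (on_s <= 0 || off_s <= 0)
    stop("invalid protocol: on_s and off_s must be positive")
  if (frame_rate_hz <= 0 || resample_rate_hz <= 0)
    stop("invalid protocol: sampling rates must be positive")
  if (is.null(central_led_indices)) {
    central_led_indices <- seq(3L, n - 1L)
  }
  central_led_indices <- as.integer(central_led_indices)
  if (any(central_led_indices < 1L) || any(central_led_indices > n))
    stop("invalid protocol: central_led_indices out of range")
  structure(list(
    led_peaks_nm = led_peaks_nm,
    led_powers_uW = led_powers_uW,
    on_s = on_s, off_s = off_s,
    n_leds = n,
    order = "long_to_short",
    frame_rate_hz = frame_rate_hz,
    resample_rate_hz = resample_rate_hz,
    baseline_s = baseline_s,
    central_led_indices = central_led_indices,
    period_s = on_s + off_s
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Spectral flash protocol:", x$n_leds, "LEDs,",
      max(x$led_peaks_nm), "->", min(x$led_peaks_nm), "nm\n")
  cat("  ", x$on_s, "s On /", x$off_s, "s Off;",
      x$frame_rate_hz, "Hz native,", x$resample_rate_hz, "Hz analysis\n")
  cat("  central LEDs:", paste(x$led_peaks_nm[x$central_led_indices],
                               collapse = ", "), "nm\n")
  invisible(x)
}

# samples per flash period at a given rate (protocol periodicity is defined on
# the sample grid; fractional-frame remainders are absorbed by rounding)
samples_per_flash <- function(protocol, rate = protocol$resample_rate_hz) {
  as.integer(round(protocol$period_s * rate))
}

# samples per full stimulus repeat (all flashes)
samples_per_repeat <- function(protocol, rate = protocol$resample_rate_hz) {
  samples_per_flash(protocol, rate) * protocol$n_leds
}
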