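# Cone spectral tuning functions ----------------------------------------------

log_bell <- function(lambda, center, width) {
  exp(-0.5 * ((log(lambda) - log(center)) / width)^2)
}

nm_bell <- function(lambda, center, width) {
  exp(-0.5 * ((lambda - center) / width)^2)
}

#' Default template parameters for the four cone spectral tunings
#'
#' Each cone is built as a dominant negative lobe (the sign convention of
#' recorded cone calcium responses to light: a dip, i.e. "Off") plus an
#' optional opposing positive lobe. Green and blue use two log-wavelength
#' bells of equal log-width, which guarantees a single sign change; the
#' opposing amplitude is solved exactly so the zero crossing lands at the
#' requested wavelength. The UV cone uses a weak wavelength-domain opposing
#' bell whose amplitude is solved for a ~450 nm crossing while keeping the
#' overshoot below 10% of the dominant peak (weak opponency). Red has no
#' opposing lobe and therefore no sign change.
#'
#' @return Named list of per-cone parameter lists.
#' @export
cone_template_params <- function() {
  list(
    red = list(center = 600, width = 0.13, crossing_nm = NA,
               opp_center = NA, opp_width = NA, opp_type = "none"),
    green = list(center = 480, width = 0.10, crossing_nm = 523,
                 opp_center = 580, opp_width = 0.10, opp_type = "log"),
    blue = list(center = 415, width = 0.09, crossing_nm = 483,
                opp_center = 500, opp_width = 0.09, opp_type = "log"),
    uv = list(center = 365, width = 0.08, crossing_nm = 450,
              opp_center = 540, opp_width = 70, opp_type = "nm")
  )
}

cone_template_curve <- function(lambda, p, led_sample = NULL) {
  lobe <- function(l, type, center, width) switch(type,
    log = log_bell(l, center, width),
    nm = nm_bell(l, center, width),
    stop("unknown opposing-lobe type"))
  neg <- function(l) log_bell(l, p$center, p$width)
  if (p$opp_type == "none") {
    if (is.null(led_sample)) return(-neg(lambda))
    return(stats::approx(led_sample, -neg(led_sample), xout = lambda,
                         rule = 2)$y)
  }
  opp <- function(l) lobe(l, p$opp_type, p$opp_center, p$opp_width)
  if (is.null(led_sample)) {
    # smooth curve: solve opposing amplitude so the curve is exactly zero at
    # the requested crossing wavelength
    a <- neg(p$crossing_nm) / opp(p$crossing_nm)
    return(-neg(lambda) + a * opp(lambda))
  }
  # measured-data format: the smooth shape sampled at the LED peaks and
  # linearly interpolated; the amplitude is solved so the *piecewise-linear*
  # curve crosses zero exactly at the requested wavelength
  nodes <- sort(led_sample)
  i <- findInterval(p$crossing_nm, nodes)
  if (i < 1 || i >= length(nodes))
    stop("requested crossing outside the LED-sampled range")
  l1 <- nodes[i]; l2 <- nodes[i + 1]; cnm <- p$crossing_nm
  a <- (neg(l1) * (l2 - cnm) + neg(l2) * (cnm - l1)) /
    (opp(l1) * (l2 - cnm) + opp(l2) * (cnm - l1))
  vals <- -neg(nodes) + a * opp(nodes)
  stats::approx(nodes, vals, xout = lambda, rule = 2)$y
}

#' Construct a set of cone spectral tuning functions
#'
#' Four spectral tuning functions (red, green, blue, UV cones) on a common
#' wavelength grid spanning 360-610 nm. In `"template"` mode smooth parametric
#' shapes are built (see [cone_template_params()]); crossings are placed
#' within 2 nm of the requested values. In `"from_file"` mode the four curves
#' are read from a CSV with columns `wavelength_nm, red, green, blue, uv`
#' (e.g. measured cone data).
#'
#' @param mode `"template"` or `"from_file"`.
#' @param wavelengths wavelength grid in nm (default 360:610).
#' @param params template parameters (see [cone_template_params()]).
#' @param led_sample wavelengths (nm) at which the template shapes are
#'   sampled before linear interpolation to the grid, emulating the format
#'   of measured cone tunings (recorded at the LED peaks and interpolated).
#'   Defaults to the standard 13 LED peaks; `NULL` gives fully smooth
#'   curves.
#' @param file CSV path for `"from_file"` mode.
#' @return An object of class `cone_tunings`: list with `wavelength_nm`
#'   (numeric grid) and `tuning` (grid x 4 matrix, columns
#'   red/green/blue/uv), plus `source`.
#' @examples
#' cones <- make_cone_tunings()
#' cone_crossings(cones)$green  # ~523 nm
#' @export
make_cone_tunings <- function(mode = c("template", "from_file"),
                              wavelengths = 360:610,
                              params = cone_template_params(),
                              led_sample = c(655, 635, 622, 592, 550, 516,
                                             501, 464, 448, 427, 407, 381,
                                             360),
                              file = NULL) {
  mode <- match.arg(mode)
  if (mode == "from_file") {
    if (is.null(file)) stop("from_file mode needs a file")
    d <- utils::read.csv(file)
    need <- c("wavelength_nm", "red", "green", "blue", "uv")
    if (!all(need %in% names(d)))
      stop("cone file must have columns: ", paste(need, collapse = ", "))
    tun <- as.matrix(d[, c("red", "green", "blue", "uv")])
    return(structure(list(wavelength_nm = d$wavelength_nm, tuning = tun,
                          source = "measured"), class = "cone_tunings"))
  }
  stopifnot(length(wavelengths) >= 2)
  for (p in params) {
    if (!is.na(p$crossing_nm) &&
        (p$crossing_nm < min(wavelengths) || p$crossing_nm > max(wavelengths)))
      stop("requested zero crossing outside wavelength grid")
  }
  tun <- vapply(params,
                function(p) cone_template_curve(wavelengths, p, led_sample),
                numeric(length(wavelengths)))
  colnames(tun) <- names(params)
  obj <- structure(list(wavelength_nm = wavelengths, tuning = tun,
                        source = "template"), class = "cone_tunings")
  # enforce the stated sign-change structure
  nsc <- vapply(names(params), function(cn)
    length(find_zero_crossings(tun[, cn], wavelengths)), integer(1))
  expected <- vapply(params, function(p) if (is.na(p$crossing_nm)) 0L else 1L,
                     integer(1))
  if (!all(nsc == expected))
    stop("cone template parameters produce an unexpected number of sign ",
         "changes: ", paste(names(params), nsc, collapse = ", "))
  obj
}

#' Zero crossings of each cone tuning
#'
#' @param cones a `cone_tunings` object.
#' @return Named list of crossing wavelengths (numeric vectors, possibly
#'   empty) per cone.
#' @export
cone_crossings <- function(cones) {
  lapply(as.data.frame(cones$tuning), function(v)
    find_zero_crossings(v, cones$wavelength_nm))
}

# evaluate cone tunings at arbitrary wavelengths; constant extrapolation
# outside the grid (the longest/shortest LEDs slightly exceed the 360-610 nm
# cone grid)
eval_cone_tunings <- function(cones, lambda) {
  out <- vapply(seq_len(ncol(cones$tuning)), function(j)
    stats::approx(cones$wavelength_nm, cones$tuning[, j], xout = lambda,
                  rule = 2)$y, numeric(length(lambda)))
  out <- matrix(out, nrow = length(lambda))
  colnames(out) <- colnames(cones$tuning)
  out
}

#' @export
print.cone_tunings <- function(x, ...) {
  cr <- cone_crossings(x)
  cat("Cone spectral tunings (", x$source, "), grid ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm\n", sep = "")
  for (cn in colnames(x$tuning))
    cat(sprintf("  %-6s crossings: %s\n", cn,
                if (length(cr[[cn]])) paste(round(cr[[cn]], 1), collapse = ", ")
                else "none"))
  invisible(x)
}

#' Plot the four cone tuning functions
#' @param x a `cone_tunings` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_cone_tunings <- function(x, ...) {
  graphics::matplot(x$wavelength_nm, x$tuning, type = "l", lty = 1,
                    col = c("red3", "green4", "blue3", "purple3"),
                    xlab = "wavelength (nm)", ylab = "response", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("bottomright", colnames(x$tuning), lty = 1,
                   col = c("red3", "green4", "blue3", "purple3"), bty = "n")
}
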