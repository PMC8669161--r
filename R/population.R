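# Ground-truth weight populations ---------------------------------------------

#' The six spectral weight archetypes
#'
#' Named list of 4 cones x 4 temporal-component weight matrices used as
#' generative archetypes for synthetic populations, one per spectral group:
#' three non-opponent (broad, red-cone-like, UV-cone-like) and three opponent
#' (green-cone aligned, blue-cone aligned, and UV versus red/green/blue).
#' Weights use the sign convention of the whole package: positive =
#' sign-inverting ("On"-like) cone input, negative = sign-conserving
#' ("Off"-like).
#'
#' Per-cone totals were chosen so each archetype's bulk spectral tuning (with
#' the default cone templates) lands in its intended group: the green/blue
#' opponent archetypes cross at the green (~523 nm) and blue (~483 nm) cone
#' template crossings, and the UV:R/G/B archetype crosses near 450 nm.
#'
#' @param component_profiles named list: per archetype, the fraction of each
#'   cone's total weight assigned to (Ltr, Lsus, Dtr, Dsus); each must sum
#'   to 1. Profiles differ across archetypes (transient vs sustained
#'   response kinetics), mirroring the temporal diversity of functional
#'   clusters; without this diversity the temporal basis would not be
#'   identifiable from the data.
#' @return Named list of six 4x4 matrices (rows red/green/blue/uv, columns
#'   Ltr/Lsus/Dtr/Dsus).
#' @export
spectral_archetypes <- function(component_profiles = list(
    broad = c(Ltr = 0.15, Lsus = 0.55, Dtr = 0.20, Dsus = 0.10),
    red_cone_like = c(Ltr = 0.50, Lsus = 0.15, Dtr = 0.30, Dsus = 0.05),
    uv_cone_like = c(Ltr = 0.20, Lsus = 0.60, Dtr = 0.10, Dsus = 0.10),
    green_opponent = c(Ltr = 0.30, Lsus = 0.40, Dtr = 0.20, Dsus = 0.10),
    blue_opponent = c(Ltr = 0.15, Lsus = 0.30, Dtr = 0.40, Dsus = 0.15),
    uv_rgb_opponent = c(Ltr = 0.35, Lsus = 0.35, Dtr = 0.15,
                        Dsus = 0.15))) {
  stopifnot(all(abs(vapply(component_profiles, sum, numeric(1)) - 1) < 1e-8))
  totals <- list(
    broad = c(red = -2.0, green = -0.3, blue = -0.3, uv = -1.5),
    red_cone_like = c(red = -2.5, green = 0, blue = 0, uv = 0),
    uv_cone_like = c(red = 0, green = 0, blue = 0, uv = 2.5),
    green_opponent = c(red = -0.3, green = -1.5, blue = 0, uv = 0),
    blue_opponent = c(red = -0.1, green = -0.1, blue = -1.5, uv = 0),
    uv_rgb_opponent = c(red = -0.5, green = 0, blue = 0, uv = 3.0)
  )
  stopifnot(setequal(names(component_profiles), names(totals)))
  out <- lapply(names(totals), function(nm)
    outer(totals[[nm]], component_profiles[[nm]]))
  names(out) <- names(totals)
  out
}

#' Generate a ground-truth population of simulated bipolar-cell terminals
#'
#' Draws per-ROI cone-weight matrices around the given archetypes (i.i.d.
#' Gaussian jitter on all 16 weights), together with IPL depths (archetype-
#' specific depth bands: Off-like archetypes stratify high, On-like UV
#' archetypes low, mirroring classical inner-retinal lamination), eye-region
#' labels, repeat count and noise level.
#'
#' @param n_rois number of simulated terminals.
#' @param archetypes named list of 4x4 weight matrices
#'   (default [spectral_archetypes()]).
#' @param proportions archetype mixing proportions (default mirrors the
#'   relative abundance of the six spectral groups among functional clusters:
#'   11/2/5/2/3/6 of 29).
#' @param depth_mean,depth_sd per-archetype IPL depth band (fraction 0-1 from
#'   the inner-nuclear-layer border).
#' @param weight_jitter SD of the Gaussian jitter added to each weight.
#' @param noise_sd SD of i.i.d. repeat-to-repeat trace noise (trace units).
#' @param n_repeats stimulus repetitions per ROI (default 7, "typically 7 to
#'   8"; configurable down to the 3-5 seen in some scans).
#' @param drift_ramp slope of the slow additive ramp (units/s, exercises
#'   linear detrending).
#' @param bleach_amp,bleach_tau optional exponential bleach amplitude and time
#'   constant (s); amplitude 0 disables.
#' @param seed RNG seed.
#' @return An object of class `bc_population`.
#' @export
make_population <- function(n_rois = 300,
                            archetypes = spectral_archetypes(),
                            proportions = c(broad = 11, red_cone_like = 2,
                                            uv_cone_like = 5,
                                            green_opponent = 2,
                                            blue_opponent = 3,
                                            uv_rgb_opponent = 6) / 29,
                            depth_mean = c(broad = 0.35, red_cone_like = 0.25,
                                           uv_cone_like = 0.80,
                                           green_opponent = 0.45,
                                           blue_opponent = 0.50,
                                           uv_rgb_opponent = 0.85),
                            depth_sd = 0.08,
                            weight_jitter = 0.10,
                            noise_sd = 0.08,
                            n_repeats = 7,
                            drift_ramp = 0.01,
                            bleach_amp = 0, bleach_tau = 20,
                            seed = 1) {
  stopifnot(n_rois >= 1, n_repeats >= 2)
  nm <- names(archetypes)
  if (!setequal(names(proportions), nm) || !setequal(names(depth_mean), nm))
    stop("proportions and depth_mean must be named like the archetypes")
  set.seed(seed)
  arch <- sample(nm, n_rois, replace = TRUE, prob = proportions[nm])
  weights <- lapply(arch, function(a) {
    w <- archetypes[[a]] +
      matrix(stats::rnorm(16, 0, weight_jitter), 4, 4)
    dimnames(w) <- dimnames(archetypes[[a]])
    w
  })
  depth <- pmin(pmax(stats::rnorm(n_rois, depth_mean[arch], depth_sd),
                     0.02), 0.98)
  # eye-region sampling: UV-dominated archetypes biased to the acute zone and
  # ventral retina, others roughly homogeneous except ventrally
  region_probs <- function(a) {
    if (a %in% c("uv_cone_like", "uv_rgb_opponent"))
      c(AZ = 0.45, D = 0.10, N = 0.15, V = 0.30)
    else c(AZ = 0.35, D = 0.22, N = 0.33, V = 0.10)
  }
  region <- vapply(arch, function(a)
    sample(c("AZ", "D", "N", "V"), 1, prob = region_probs(a)), character(1))
  structure(list(
    n_rois = n_rois,
    weights = weights,
    archetype = factor(arch, levels = nm),
    cluster_id = as.integer(factor(arch, levels = nm)),
    ipl_depth = as.numeric(depth),
    region = factor(region, levels = c("AZ", "D", "N", "V")),
    weight_jitter = weight_jitter,
    noise_sd = noise_sd,
    n_repeats = as.integer(n_repeats),
    drift_ramp = drift_ramp,
    bleach_amp = bleach_amp, bleach_tau = bleach_tau,
    seed = seed
  ), class = "bc_population")
}

#' @export
print.bc_population <- function(x, ...) {
  cat("Synthetic BC population:", x$n_rois, "ROIs,", x$n_repeats,
      "repeats, noise_sd =", x$noise_sd, "\n")
  print(table(x$archetype))
  invisible(x)
}
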