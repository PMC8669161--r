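# Spectral tuning analysis: crossings, opponency, spectral groups -------------

#' Bulk spectral tuning from a weight matrix
#'
#' Sums the sixteen cone-tuning functions, each scaled by the corresponding
#' weight, giving equal weight to each of the four temporal components:
#' `curve(lambda) = sum_c sum_k w[c,k] * S_c(lambda)`. Optionally returns the
#' four per-component curves.
#'
#' @param W `cone_weights` (normalized copy is used) or a 4x4 weight matrix
#'   (rows = cones).
#' @param cone_set a `cone_tunings`.
#' @param per_component if TRUE, also return a wavelength x 4 matrix of
#'   per-component curves.
#' @return Numeric curve on the cone grid, or a list
#'   `(curve, per_component_curves)` when `per_component = TRUE`.
#' @export
bulk_tuning <- function(W, cone_set, per_component = FALSE) {
  if (inherits(W, "cone_weights")) W <- W$w_norm
  curve <- as.vector(cone_set$tuning %*% rowSums(W))
  if (!per_component) return(curve)
  list(curve = curve, per_component_curves = cone_set$tuning %*% W)
}

#' Zero crossings of a spectral curve
#'
#' Sign-change locations, linearly interpolated between grid points.
#'
#' @param curve numeric curve, finite.
#' @param wavelengths corresponding wavelength grid (nm).
#' @return Numeric vector of crossing wavelengths (possibly empty).
#' @export
find_zero_crossings <- function(curve, wavelengths) {
  stopifnot(all(is.finite(curve)), length(curve) == length(wavelengths))
  s <- sign(curve)
  # treat exact zeros as crossings when flanked by opposite signs
  out <- numeric(0)
  nz <- which(s != 0)
  if (length(nz) < 2) return(out)
  for (i in seq_len(length(nz) - 1)) {
    a <- nz[i]; b <- nz[i + 1]
    if (s[a] * s[b] < 0) {
      if (b == a + 1) {
        out <- c(out, wavelengths[a] - curve[a] *
                   (wavelengths[b] - wavelengths[a]) / (curve[b] - curve[a]))
      } else {
        # exact zero(s) between: report the zero location(s) midpoint
        out <- c(out, mean(wavelengths[(a + 1):(b - 1)]))
      }
    }
  }
  out
}

#' Classify spectral opponency of a tuning curve
#'
#' The dominant polarity is the sign of the curve at its global absolute
#' peak. The curve is opponent iff it crosses zero and overshoots with an
#' opposite-polarity extremum of amplitude at least `threshold` (inclusive)
#' times the dominant peak; crossings adjacent to such a qualifying opposite
#' lobe are returned as qualifying crossings.
#'
#' @param curve numeric curve (not all zero).
#' @param wavelengths wavelength grid (nm).
#' @param threshold opponency amplitude threshold, default 0.10 (inclusive).
#' @return List: `is_opponent`, `crossings` (all), `qualifying_crossings`,
#'   `dominant_sign`, `dominant_peak`, `opposite_peak`.
#' @export
classify_opponency <- function(curve, wavelengths, threshold = 0.10) {
  if (all(curve == 0)) stop("zero curve: opponency undefined")
  imax <- which.max(abs(curve))
  dom_sign <- sign(curve[imax])
  dom_peak <- abs(curve[imax])
  crossings <- find_zero_crossings(curve, wavelengths)
  if (!length(crossings))
    return(list(is_opponent = FALSE, crossings = numeric(0),
                qualifying_crossings = numeric(0), dominant_sign = dom_sign,
                dominant_peak = dom_peak, opposite_peak = 0))
  # segment the curve at crossings; find each segment's extremum
  bounds <- c(min(wavelengths) - 1, crossings, max(wavelengths) + 1)
  seg_ext <- numeric(length(bounds) - 1)
  for (i in seq_along(seg_ext)) {
    in_seg <- wavelengths > bounds[i] & wavelengths <= bounds[i + 1]
    seg_ext[i] <- if (any(in_seg)) curve[in_seg][which.max(abs(curve[in_seg]))]
    else 0
  }
  qual <- logical(length(crossings))
  tol <- 1e-12
  for (i in seq_along(crossings)) {
    for (seg in c(i, i + 1)) {               # segments adjacent to crossing i
      if (sign(seg_ext[seg]) == -dom_sign &&
          abs(seg_ext[seg]) >= threshold * dom_peak - tol)
        qual[i] <- TRUE
    }
  }
  opp_peak <- max(c(0, abs(seg_ext[sign(seg_ext) == -dom_sign])))
  list(is_opponent = any(qual), crossings = crossings,
       qualifying_crossings = crossings[qual],
       dominant_sign = dom_sign, dominant_peak = dom_peak,
       opposite_peak = opp_peak)
}

#' Assign a spectral group to a tuning curve
#'
#' Opponent curves are grouped by the position of their strongest qualifying
#' zero crossing: >= 510 nm green-opponent, 470-510 nm blue-opponent,
#' < 470 nm UV:R/G/B-opponent. Non-opponent curves go to whichever of the
#' red-cone template, UV-cone template or a flat broadband profile they
#' resemble most (absolute cosine similarity; ties break toward broad).
#'
#' @param curve numeric tuning curve on the cone grid.
#' @param cone_set a `cone_tunings` (templates for the non-opponent match).
#' @param bands cut points `c(uv_blue = 470, blue_green = 510)` in nm.
#' @param threshold opponency threshold (see [classify_opponency()]).
#' @return One of `"broad"`, `"red_cone_like"`, `"uv_cone_like"`,
#'   `"green_opponent"`, `"blue_opponent"`, `"uv_rgb_opponent"`.
#' @export
assign_spectral_group <- function(curve, cone_set,
                                  bands = c(uv_blue = 470, blue_green = 510),
                                  threshold = 0.10) {
  wl <- cone_set$wavelength_nm
  opp <- classify_opponency(curve, wl, threshold)
  if (opp$is_opponent) {
    # pick the qualifying crossing with the largest adjacent opposite lobe:
    # approximate by the qualifying crossing closest to the opposite-polarity
    # global extremum
    qc <- opp$qualifying_crossings
    iopp <- which.max(abs(curve) * (sign(curve) == -opp$dominant_sign))
    cr <- qc[which.min(abs(qc - wl[iopp]))]
    if (cr >= bands["blue_green"]) return("green_opponent")
    if (cr >= bands["uv_blue"]) return("blue_opponent")
    return("uv_rgb_opponent")
  }
  cossim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  sims <- c(broad = cossim(curve, rep(1, length(curve))),
            red_cone_like = cossim(curve, cone_set$tuning[, "red"]),
            uv_cone_like = cossim(curve, cone_set$tuning[, "uv"]))
  # ties break toward broad (it is listed first)
  names(sims)[which.max(sims)]
}

#' ROI-abundance-weighted histogram of zero crossings
#'
#' Each opponent cluster contributes its ROI count, split equally over its
#' qualifying crossings; non-opponent clusters contribute nothing, so the
#' total mass equals the summed ROI counts of opponent clusters. In
#' `per_component` mode each component's own tuning curve is used (mass per
#' cluster is then counted once per opponent component curve).
#'
#' @param tunings list of bulk curves (mode `"bulk"`), or list of
#'   wavelength x 4 per-component curve matrices (mode `"per_component"`).
#' @param roi_counts ROI abundance per cluster.
#' @param wavelengths wavelength grid of the curves (nm).
#' @param mode `"bulk"` or `"per_component"`.
#' @param breaks histogram breaks (nm), default 5-nm bins over 360-610.
#' @param threshold opponency threshold.
#' @return List with `breaks`, `mids`, `counts`, `total_mass`.
#' @export
zero_crossing_histogram <- function(tunings, roi_counts, wavelengths,
                                    mode = c("bulk", "per_component"),
                                    breaks = seq(360, 610, by = 5),
                                    threshold = 0.10) {
  mode <- match.arg(mode)
  stopifnot(length(tunings) == length(roi_counts))
  counts <- rep(0, length(breaks) - 1)
  add_mass <- function(curve, mass) {
    if (all(curve == 0)) return(invisible())
    opp <- classify_opponency(curve, wavelengths, threshold)
    qc <- opp$qualifying_crossings
    if (!opp$is_opponent || !length(qc)) return(invisible())
    for (cr in qc) {
      bin <- findInterval(cr, breaks, rightmost.closed = TRUE)
      if (bin >= 1 && bin <= length(counts))
        counts[bin] <<- counts[bin] + mass / length(qc)
    }
  }
  for (i in seq_along(tunings)) {
    if (mode == "bulk") add_mass(tunings[[i]], roi_counts[i])
    else apply(tunings[[i]], 2, add_mass, mass = roi_counts[i])
  }
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts, total_mass = sum(counts))
}

#' Trimodality score of a crossing histogram
#'
#' Ratio of the weakest of the three dominant peaks of the (moving-average
#' smoothed) histogram to the mean histogram level. Three strong, distinct
#' modes give a high score; a histogram with mass spread diffusely, or
#' concentrated in fewer than three modes, scores low (0 when there is no
#' mass or fewer than three local maxima).
#'
#' @param hist result of [zero_crossing_histogram()], or a numeric count
#'   vector.
#' @return Scalar score.
#' @export
trimodality_score <- function(hist) {
  counts <- if (is.list(hist)) hist$counts else hist
  if (sum(counts) == 0) return(0)
  k <- stats::filter(c(0, counts, 0), rep(1 / 3, 3), sides = 2)
  sm <- as.numeric(k[2:(length(counts) + 1)])
  sm[is.na(sm)] <- 0
  is_max <- vapply(seq_along(sm), function(i) {
    l <- if (i > 1) sm[i - 1] else -Inf
    r <- if (i < length(sm)) sm[i + 1] else -Inf
    sm[i] > 0 && sm[i] >= l && sm[i] >= r
  }, logical(1))
  peaks <- sort(sm[is_max], decreasing = TRUE)
  top3 <- c(peaks, 0, 0, 0)[1:3]
  min(top3) / (mean(sm) + 1e-9)
}

#' Randomization controls for the crossing histogram
#'
#' Null distributions of the zero-crossing histogram under (a) full weight
#' randomization (`"randomize"`: each cluster's 16 weights resampled with
#' replacement from the pooled weight values of all clusters) or (b)
#' permutation of the four-component weight blocks across cones
#' (`"shuffle_across_cones"`). Recomputes the bulk-crossing histogram per
#' iterate.
#'
#' @param weight_list list of 4x4 weight matrices (one per cluster).
#' @param cone_set a `cone_tunings`.
#' @param roi_counts ROI abundance per cluster.
#' @param mode `"randomize"` or `"shuffle_across_cones"`.
#' @param n_iter number of null iterates (>= 1).
#' @param seed RNG seed.
#' @param ... passed to [zero_crossing_histogram()].
#' @return List with `mode`, `histograms` (list per iterate), `mean_counts`,
#'   `scores` (trimodality per iterate).
#' @export
randomization_controls <- function(weight_list, cone_set, roi_counts,
                                   mode = c("randomize",
                                            "shuffle_across_cones"),
                                   n_iter = 100, seed = 1, ...) {
  mode <- match.arg(mode)
  stopifnot(n_iter >= 1)
  set.seed(seed)
  pool <- unlist(lapply(weight_list, as.vector))
  wl <- cone_set$wavelength_nm
  hists <- vector("list", n_iter)
  scores <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    wnull <- lapply(weight_list, function(W) {
      if (mode == "randomize") {
        Wn <- matrix(sample(pool, 16, replace = TRUE), 4, 4)
        dimnames(Wn) <- dimnames(W)
        Wn
      } else {
        W[sample(4), , drop = FALSE]         # permute cone rows
      }
    })
    curves <- lapply(wnull, bulk_tuning, cone_set = cone_set)
    hists[[it]] <- zero_crossing_histogram(curves, roi_counts, wl, ...)
    scores[it] <- trimodality_score(hists[[it]])
  }
  mean_counts <- Reduce(`+`, lapply(hists, `[[`, "counts")) / n_iter
  list(mode = mode, histograms = hists, mean_counts = mean_counts,
       scores = scores)
}
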