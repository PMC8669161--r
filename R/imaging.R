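# Image-domain preprocessing: IPL detection, QI images, ROI placement ---------

# separable Gaussian smoothing with edge replication
smooth2d_gaussian <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  conv1 <- function(v) {
    # replicate-pad then convolve
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + length(v))]
  }
  img <- apply(img, 2, conv1)
  t(apply(t(img), 2, conv1))
}

# 3x3 median filter (config alternative to Gaussian smoothing)
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- stats::median(img[max(1, i - 1):min(nr, i + 1),
                                   max(1, j - 1):min(nc, j + 1)])
  }
  out
}

# box-filter local mean (edge-replicated), used for adaptive thresholding
local_mean <- function(img, size = 5) {
  half <- size %/% 2
  csum <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::filter(vp, rep(1 / size, size),
                  sides = 2)[(half + 1):(half + length(v))]
  }
  img <- apply(img, 2, csum)
  t(apply(t(img), 2, csum))
}

# two-pass city-block distance transform: distance to nearest FALSE pixel
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- nr + nc
  d <- ifelse(mask, big, 0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (d[i, j] > 0) {
      up <- if (i > 1) d[i - 1, j] else 0
      lf <- if (j > 1) d[i, j - 1] else 0
      d[i, j] <- min(d[i, j], up + 1, lf + 1)
    }
  }
  for (i in rev(seq_len(nr))) for (j in rev(seq_len(nc))) {
    if (d[i, j] > 0) {
      dn <- if (i < nr) d[i + 1, j] else 0
      rt <- if (j < nc) d[i, j + 1] else 0
      d[i, j] <- min(d[i, j], dn + 1, rt + 1)
    }
  }
  d
}

# 8-connected component labelling via flood fill
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# time-SD image per plane of a (T, y, x[, plane]) stack
time_sd_images <- function(stack) {
  if (length(dim(stack)) == 3) stack <- array(stack, c(dim(stack), 1))
  d <- dim(stack)
  lapply(seq_len(d[4]), function(pl) {
    m <- matrix(stack[, , , pl], nrow = d[1])
    sdv <- sqrt(pmax(colMeans(m^2) - colMeans(m)^2, 0))
    matrix(sdv, d[2], d[3])
  })
}

#' Detect the inner plexiform layer in a fluorescence stack
#'
#' Computes the per-pixel temporal standard deviation of each plane, smooths
#' it (Gaussian, sigma derived from a 3-px kernel; a 3x3 median filter is
#' available behind `method`), and registers every pixel above the 35%
#' per-image relative amplitude threshold (`min + 0.35 * (max - min)`) as
#' IPL. Border curves are the mask's outer (top) and inner (bottom) row per
#' column.
#'
#' @param stack array (time, y, x) or (time, y, x, plane); at least 2 time
#'   points. A `synthetic_scene` is also accepted.
#' @param threshold relative amplitude threshold, default 0.35.
#' @param method smoothing method, `"gaussian"` (default) or `"median"`.
#' @param kernel_px nominal kernel size in pixels (FWHM for Gaussian).
#' @return List (one element per plane) of lists with `mask` (logical y x x),
#'   `top`, `bottom` (numeric per column, NA where the column has no IPL).
#' @export
detect_ipl <- function(stack, threshold = 0.35,
                       method = c("gaussian", "median"), kernel_px = 3) {
  method <- match.arg(method)
  if (inherits(stack, "synthetic_scene")) stack <- stack$stack
  if (dim(stack)[1] < 2) stop("stack needs at least 2 time points")
  sds <- time_sd_images(stack)
  lapply(sds, function(sd_img) {
    sm <- if (method == "gaussian")
      smooth2d_gaussian(sd_img, sigma = kernel_px / 2.355)
    else median_filter3(sd_img)
    rng <- range(sm)
    if (diff(rng) == 0) stop("no IPL detected: uniform-intensity image")
    mask <- sm > rng[1] + threshold * diff(rng)
    if (!any(mask)) stop("no IPL detected: empty mask")
    top <- apply(mask, 2, function(col) if (any(col)) min(which(col)) else NA)
    bottom <- apply(mask, 2, function(col) if (any(col)) max(which(col)) else NA)
    list(mask = mask, top = top, bottom = bottom)
  })
}

#' Per-pixel quality-index image
#'
#' Folds each pixel's time course into stimulus repeats (discarding the
#' pre-stimulus baseline) and computes the repeat-coherence QI per pixel.
#'
#' @param stack array (time, y, x) or (time, y, x, plane), or a
#'   `synthetic_scene` (then the remaining arguments default from it).
#' @param samples_per_rep samples per stimulus repeat at the stack's rate.
#' @param n_baseline leading samples to discard before folding.
#' @return List of QI matrices (one per plane), values in \[0, 1\]; pixels
#'   with undefined QI (constant) are set to 0.
#' @export
qi_image <- function(stack, samples_per_rep = NULL, n_baseline = 0) {
  if (inherits(stack, "synthetic_scene")) {
    sc <- stack
    samples_per_rep <- samples_per_repeat(sc$protocol, sc$rate_hz)
    n_baseline <- sc$n_baseline_samples
    stack <- sc$stack
  }
  if (is.null(samples_per_rep)) stop("samples_per_rep required")
  if (length(dim(stack)) == 3) stack <- array(stack, c(dim(stack), 1))
  d <- dim(stack)
  if ((d[1] - n_baseline) %/% samples_per_rep < 2)
    stop("fewer than 2 repeats in stack")
  lapply(seq_len(d[4]), function(pl) {
    m <- matrix(stack[, , , pl], nrow = d[1])
    if (n_baseline > 0) m <- m[-seq_len(n_baseline), , drop = FALSE]
    R <- nrow(m) %/% samples_per_rep
    m <- m[seq_len(R * samples_per_rep), , drop = FALSE]
    qi <- apply(m, 2, function(px) {
      C <- matrix(px, nrow = samples_per_rep)
      within <- mean(apply(C, 2, stats::var))
      if (within == 0) return(0)
      stats::var(rowMeans(C)) / within
    })
    matrix(qi, d[2], d[3])
  })
}

#' Place ROIs on a quality-index image
#'
#' Adaptive thresholding (local-mean filter, default 5-px block, accentuating
#' terminal-sized structures) combined with a global QI floor gives a binary
#' image; it is distance-transformed and shrunk to cores more than 1 px from
#' the background, and the surviving connected components are re-filled from
#' the binary image and recorded as ROI pixel sets.
#'
#' @param qmap QI matrix (y x x), finite.
#' @param block adaptive-threshold block size in px, default 5.
#' @param offset adaptive-threshold offset, default 0.
#' @param qi_floor global floor on QI for candidate pixels, default 0.4
#'   (matching the ROI-level keep threshold; it also prevents the weakly
#'   coherent neuropil from percolating into band-wide components).
#' @param core_dist minimum city-block distance defining ROI cores,
#'   default > 1 px.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param max_area_px optional upper bound on ROI area (px); larger
#'   components are dropped.
#' @return List of ROIs, each a list with `pixels` (n x 2 matrix of row/col),
#'   `center` (row/col center of mass), `area_um2`.
#' @export
place_rois <- function(qmap, block = 5, offset = 0, qi_floor = 0.4,
                       core_dist = 1, pixel_size_um = 0.26,
                       max_area_px = 200) {
  stopifnot(all(is.finite(qmap)))
  if (!any(qmap > qi_floor)) return(list())
  B <- (qmap > local_mean(qmap, block) + offset) & (qmap > qi_floor)
  if (!any(B)) return(list())
  D <- distance_transform(B)
  cores <- D > core_dist
  lab <- label_components(B)
  keep <- sort(unique(lab$labels[cores]))
  keep <- setdiff(keep, 0L)
  out <- lapply(keep, function(l) {
    px <- which(lab$labels == l, arr.ind = TRUE)
    if (nrow(px) > max_area_px) return(NULL)
    list(pixels = px,
         center = colMeans(px),
         area_um2 = nrow(px) * pixel_size_um^2)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Extract quality-filtered ROI records from a synthetic scene
#'
#' Full image-domain preprocessing: per plane, detect the IPL, compute the QI
#' image, place ROIs, average each ROI's pixels, detrend and resample the
#' trace to the analysis rate, z-score it against the pre-stimulus baseline,
#' fold into repeats and compute the ROI-level QI and IPL depth (center of
#' mass relative to the nearest IPL borders; 0 = inner-nuclear-layer side).
#'
#' @param scene a `synthetic_scene`.
#' @param target_rate analysis sampling rate (Hz), default from the protocol.
#' @param qi_min quality threshold passed to [filter_rois()]; set to 0 to
#'   keep everything.
#' @param ... passed to [place_rois()].
#' @return List of `roi_record`s (kept subset), each with `trace_mean`,
#'   `trace_repeats`, `qi`, `ipl_depth`, `plane`, `center`, `area_um2`.
#' @export
extract_rois_from_scene <- function(scene,
                                    target_rate =
                                      scene$protocol$resample_rate_hz,
                                    qi_min = 0.4, ...) {
  ipl <- detect_ipl(scene$stack)
  qmaps <- qi_image(scene)
  per_rep_t <- samples_per_repeat(scene$protocol, target_rate)
  n_base_t <- round(scene$protocol$baseline_s * target_rate)
  records <- list()
  for (pl in seq_along(qmaps)) {
    rois <- place_rois(qmaps[[pl]], pixel_size_um = scene$pixel_size_um, ...)
    d <- dim(scene$stack)
    m <- matrix(scene$stack[, , , pl], nrow = d[1])
    for (roi in rois) {
      lin <- (roi$pixels[, 2] - 1) * d[2] + roi$pixels[, 1]
      raw <- rowMeans(m[, lin, drop = FALSE])
      tr <- detrend_and_resample(raw, scene$rate_hz, target_rate)
      z <- tryCatch(zscore_trace(tr, baseline_n = n_base_t),
                    error = function(e) NULL)
      if (is.null(z)) next
      body <- z[-seq_len(n_base_t)]
      C <- tryCatch(fold_repeats(body, per_rep_t), error = function(e) NULL)
      if (is.null(C)) next
      qi <- tryCatch(compute_qi(C), error = function(e) 0)
      col <- round(roi$center[2])
      top <- ipl[[pl]]$top[col]; bottom <- ipl[[pl]]$bottom[col]
      depth <- if (is.na(top) || is.na(bottom) || bottom <= top) NA_real_
      else min(max((roi$center[1] - top) / (bottom - top), 0), 1)
      records[[length(records) + 1]] <- structure(list(
        id = length(records) + 1,
        plane = pl, center = roi$center, area_um2 = roi$area_um2,
        trace_repeats = C, trace_mean = rowMeans(C),
        qi = qi, ipl_depth = depth
      ), class = "roi_record")
    }
  }
  filter_rois(records, qi_min)
}
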