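# Reconstruction quality and weight statistics --------------------------------

#' Fraction of across-cluster variance captured by reconstructions
#'
#' Computes, per time point, the variance across clusters for the original
#' means, the reconstructions and the residuals (original - reconstruction);
#' the reported percentages are the areas under these variance traces
#' normalized to the original one.
#'
#' @param cluster_means matrix, clusters x time.
#' @param reconstructions matrix of the same shape.
#' @return List of class `fit_quality` with `variance_explained_pct`,
#'   `residual_variance_pct` and the three variance traces.
#' @export
variance_explained <- function(cluster_means, reconstructions) {
  M <- as.matrix(cluster_means); Rc <- as.matrix(reconstructions)
  if (!all(dim(M) == dim(Rc))) stop("shape mismatch")
  v <- function(x) apply(x, 2, stats::var)
  v_orig <- v(M)
  if (sum(v_orig) == 0) stop("zero original variance")
  v_rec <- v(Rc)
  v_res <- v(M - Rc)
  structure(list(variance_explained_pct = 100 * sum(v_rec) / sum(v_orig),
                 residual_variance_pct = 100 * sum(v_res) / sum(v_orig),
                 variance_traces = list(original = v_orig,
                                        reconstruction = v_rec,
                                        residual = v_res)),
            class = "fit_quality")
}

# mean band-limited power spectrum over traces (rows); mean removed per
# trace, rectangular window
band_power_spectrum <- function(M, rate, band) {
  T_ <- ncol(M)
  freq <- (seq_len(T_) - 1) * rate / T_
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stop("band outside the resolvable frequency range")
  P <- t(apply(M, 1, function(x) Mod(stats::fft(x - mean(x)))^2))
  list(freq = freq[sel], power = colMeans(P[, sel, drop = FALSE]))
}

#' Fraction of band-limited temporal power captured by reconstructions
#'
#' Magnitude-squared Fourier transform of each trace (mean removed,
#' rectangular window), restricted to `band` (default 0.16-2 Hz, the
#' physiologically meaningful range given slow indicator kinetics below and
#' detrending artifacts above), averaged over clusters; percentages are AUC
#' ratios against the originals and may exceed 100.
#'
#' @param cluster_means,reconstructions matrices, clusters x time.
#' @param rate sampling rate (Hz).
#' @param band frequency band in Hz, default `c(0.16, 2)`.
#' @return List of class `fit_quality` with `power_explained_pct`,
#'   `residual_power_pct`, `band_hz` and the mean spectra.
#' @export
power_explained <- function(cluster_means, reconstructions, rate = 42,
                            band = c(0.16, 2)) {
  M <- as.matrix(cluster_means); Rc <- as.matrix(reconstructions)
  if (!all(dim(M) == dim(Rc))) stop("shape mismatch")
  if (band[2] > rate / 2) stop("band outside Nyquist")
  sp_o <- band_power_spectrum(M, rate, band)
  sp_r <- band_power_spectrum(Rc, rate, band)
  sp_e <- band_power_spectrum(M - Rc, rate, band)
  auc_o <- sum(sp_o$power)
  if (auc_o == 0) stop("zero original band power")
  structure(list(power_explained_pct = 100 * sum(sp_r$power) / auc_o,
                 residual_power_pct = 100 * sum(sp_e$power) / auc_o,
                 band_hz = band,
                 spectra = list(freq = sp_o$freq, original = sp_o$power,
                                reconstruction = sp_r$power,
                                residual = sp_e$power)),
            class = "fit_quality")
}

# weight tables: one row per cluster (or ROI), 16 columns named
# w_<cone>_<component>
weight_colnames <- function() {
  as.vector(outer(c("red", "green", "blue", "uv"),
                  c("Ltr", "Lsus", "Dtr", "Dsus"),
                  function(a, b) paste0("w_", a, "_", b)))
}

#' Convert a list of weight matrices to a weight table
#' @param weight_list list of 4x4 matrices (rows cones, cols components).
#' @return data.frame with 16 `w_<cone>_<component>` columns.
#' @export
weights_to_table <- function(weight_list) {
  out <- as.data.frame(t(vapply(weight_list, function(W) as.vector(W),
                                numeric(16))))
  names(out) <- weight_colnames()
  out
}

table_to_weights <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i)
    matrix(as.numeric(tab[i, weight_colnames()]), 4, 4,
           dimnames = list(c("red", "green", "blue", "uv"),
                           c("Ltr", "Lsus", "Dtr", "Dsus"))))
}

#' Absolute-weight summaries and paired rank tests
#'
#' Mean and SD of |w| per cone (pooling the four temporal components) and
#' per component (pooling cones), plus rank-based paired tests between all
#' cone pairs, pairing matched components within clusters (red-Ltr versus
#' green-Ltr, and so on). All weights contribute equally, independent of
#' cluster size. The default test is the Wilcoxon signed-rank on the paired
#' values; a rank-sum variant is available.
#'
#' @param weight_table data.frame with the 16 `w_*` columns, one row per
#'   cluster (>= 2).
#' @param test `"signed_rank"` (paired; default) or `"rank_sum"`.
#' @return List with `cone_stats`, `component_stats` (data.frames with
#'   mean/sd of |w|), `tests` (data.frame: pair, p_value).
#' @export
weight_statistics <- function(weight_table,
                              test = c("signed_rank", "rank_sum")) {
  test <- match.arg(test)
  if (nrow(weight_table) < 2) stop("need at least 2 clusters")
  cones <- c("red", "green", "blue", "uv")
  comps <- c("Ltr", "Lsus", "Dtr", "Dsus")
  absw <- function(cone) {
    cols <- paste0("w_", cone, "_", comps)
    as.vector(abs(as.matrix(weight_table[, cols])))
  }
  cone_stats <- data.frame(
    cone = cones,
    mean_abs_w = vapply(cones, function(cn) mean(absw(cn)), numeric(1)),
    sd_abs_w = vapply(cones, function(cn) stats::sd(absw(cn)), numeric(1)))
  comp_stats <- data.frame(
    component = comps,
    mean_abs_w = vapply(comps, function(k)
      mean(abs(as.matrix(weight_table[, paste0("w_", cones, "_", k)]))),
      numeric(1)),
    sd_abs_w = vapply(comps, function(k)
      stats::sd(abs(as.matrix(weight_table[, paste0("w_", cones, "_", k)]))),
      numeric(1)))
  pairs <- utils::combn(cones, 2)
  tests <- data.frame(
    pair = apply(pairs, 2, paste, collapse = ":"),
    p_value = apply(pairs, 2, function(pr) {
      x <- absw(pr[1]); y <- absw(pr[2])
      suppressWarnings(
        stats::wilcox.test(x, y, paired = test == "signed_rank",
                           exact = FALSE)$p.value)
    }))
  list(cone_stats = cone_stats, component_stats = comp_stats, tests = tests)
}

#' Pairwise Pearson correlations between per-cluster mean cone weights
#'
#' The mean weight per cone (over the four temporal components, signed) is
#' computed per cluster; Pearson's rho and Fisher-z 95% confidence intervals
#' are reported for all six cone pairs.
#'
#' @param weight_table data.frame with the 16 `w_*` columns, one row per
#'   cluster (>= 4).
#' @return data.frame: pair, rho, ci_lo, ci_hi.
#' @export
weight_correlations <- function(weight_table) {
  if (nrow(weight_table) < 4) stop("need at least 4 clusters")
  cones <- c("red", "green", "blue", "uv")
  comps <- c("Ltr", "Lsus", "Dtr", "Dsus")
  mw <- vapply(cones, function(cn)
    rowMeans(as.matrix(weight_table[, paste0("w_", cn, "_", comps)])),
    numeric(nrow(weight_table)))
  pairs <- utils::combn(cones, 2)
  out <- apply(pairs, 2, function(pr) {
    ct <- stats::cor.test(mw[, pr[1]], mw[, pr[2]])
    c(rho = unname(ct$estimate), ci_lo = ct$conf.int[1],
      ci_hi = ct$conf.int[2])
  })
  data.frame(pair = apply(pairs, 2, paste, collapse = ":"),
             t(out))
}

#' Two-dimensional weight-by-IPL-depth histograms and polarity violations
#'
#' Pools the two light-component weights (Ltr, Lsus) or the two
#' dark-component weights (Dtr, Dsus) per cone and bins them against IPL
#' depth, excluding near-zero weights (|w| < 0.5). Classical inner-retinal
#' lamination expects sign-conserving (negative) light weights in the upper
#' IPL (depth < 0.5) and sign-inverting (positive) below, and the reverse
#' for dark components; entries contradicting this are summarized as
#' polarity-violation fractions per depth tercile.
#'
#' @param weight_table data.frame with the 16 `w_*` columns, one row per ROI.
#' @param depths IPL depths in \[0,1\], one per row.
#' @param combine `"light"` or `"dark"`.
#' @param near_zero exclusion threshold on |w|, default 0.5.
#' @param w_breaks,d_breaks histogram breaks for weight and depth.
#' @return List with `hist` (named list per cone of weight x depth count
#'   matrices), `violations` (data.frame cone x tercile fraction), `n_shown`
#'   (entries with |w| >= near_zero).
#' @export
weight_ipl_histogram <- function(weight_table, depths,
                                 combine = c("light", "dark"),
                                 near_zero = 0.5,
                                 w_breaks = seq(-6, 6, by = 0.5),
                                 d_breaks = seq(0, 1, by = 0.1)) {
  combine <- match.arg(combine)
  stopifnot(nrow(weight_table) == length(depths),
            all(depths >= 0 & depths <= 1))
  comps <- if (combine == "light") c("Ltr", "Lsus") else c("Dtr", "Dsus")
  cones <- c("red", "green", "blue", "uv")
  # expected sign at depth: light components negative (sign-conserving) in
  # the upper/Off half, positive below; dark components the reverse
  expected_sign <- function(d) {
    s <- ifelse(d < 0.5, -1, 1)
    if (combine == "dark") -s else s
  }
  hists <- list(); viol <- NULL; n_shown <- 0
  terc <- cut(depths, breaks = c(0, 1 / 3, 2 / 3, 1), include.lowest = TRUE,
              labels = c("upper", "middle", "lower"))
  for (cn in cones) {
    w <- as.matrix(weight_table[, paste0("w_", cn, "_", comps)])
    keep <- abs(w) >= near_zero
    H <- matrix(0, length(w_breaks) - 1, length(d_breaks) - 1)
    dd <- matrix(depths, nrow(w), ncol(w))
    tt <- matrix(as.integer(terc), nrow(w), ncol(w))
    wv <- pmin(pmax(w[keep], min(w_breaks)), max(w_breaks))
    dv <- dd[keep]
    wi <- findInterval(wv, w_breaks, rightmost.closed = TRUE)
    di <- findInterval(dv, d_breaks, rightmost.closed = TRUE)
    for (i in seq_along(wv)) H[wi[i], di[i]] <- H[wi[i], di[i]] + 1
    hists[[cn]] <- H
    n_shown <- n_shown + sum(keep)
    bad <- sign(w[keep]) != expected_sign(dv)
    vf <- vapply(1:3, function(tz) {
      sel <- tt[keep] == tz
      if (!any(sel)) return(NA_real_)
      mean(bad[sel])
    }, numeric(1))
    viol <- rbind(viol, data.frame(cone = cn, upper = vf[1], middle = vf[2],
                                   lower = vf[3]))
  }
  list(hist = hists, violations = viol, n_shown = n_shown,
       w_breaks = w_breaks, d_breaks = d_breaks, combine = combine,
       near_zero = near_zero)
}
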