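# Non-negative matrix factorization (multiplicative updates) ------------------

# V (n x m, non-negative) ~ W (n x k) H (k x m); Frobenius objective,
# classical multiplicative updates with restarts, keeping the lowest
# reconstruction error. Deterministic given `seed`.
nmf_mu <- function(V, k, n_iter = 400, n_restarts = 20, seed = 1,
                   eps = 1e-9) {
  stopifnot(all(V >= 0), k >= 1)
  n <- nrow(V); m <- ncol(V)
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(V) + eps)
    H <- matrix(stats::runif(k * m, 0.1, 1), k, m) * sqrt(mean(V) + eps)
    for (it in seq_len(n_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    }
    err <- sum((V - W %*% H)^2)
    if (is.null(best) || err < best$err) best <- list(W = W, H = H, err = err)
  }
  best$rel_err <- best$err / max(sum(V^2), eps)
  best
}

#' Extract the temporal basis from responses by NMF
#'
#' Cuts every trace into flash-period snippets, offsets each snippet by its
#' minimum (non-negativity), factorizes the snippet matrix by multiplicative-
#' update NMF into `n_components` non-negative temporal kernels, L2-normalizes
#' them, and labels them light/dark (by On- vs Off-window support mass) and
#' transient/sustained (by peak-to-plateau ratio), returning them in the
#' canonical order Ltr, Lsus, Dtr, Dsus.
#'
#' @param traces matrix of flash-aligned responses, one row per trace
#'   (e.g. cluster means over the full stimulus), covering whole flash
#'   periods at `rate`.
#' @param protocol a `stim_protocol`.
#' @param n_components number of kernels, default 4.
#' @param rate sampling rate of `traces` (Hz).
#' @param seed RNG seed for the NMF restarts.
#' @param max_rel_err error threshold beyond which the factorization is
#'   declared non-convergent.
#' @return A `temporal_basis` whose kernels come from the data.
#' @export
extract_temporal_basis_nmf <- function(traces, protocol, n_components = 4,
                                       rate = protocol$resample_rate_hz,
                                       seed = 1, max_rel_err = 0.9) {
  traces <- as.matrix(traces)
  if (all(traces == 0)) stop("all-zero input: no temporal structure to factorize")
  P <- samples_per_flash(protocol, rate)
  if (ncol(traces) %% P != 0)
    stop("traces do not cover whole flash periods")
  n_fl <- ncol(traces) %/% P
  snips <- do.call(rbind, lapply(seq_len(n_fl), function(f)
    traces[, ((f - 1) * P + 1):(f * P), drop = FALSE]))
  snips <- snips - apply(snips, 1, min)      # shift each snippet >= 0
  keep <- rowSums(snips) > 0
  snips <- snips[keep, , drop = FALSE]
  if (nrow(snips) < n_components)
    stop("not enough non-degenerate snippets for NMF")
  fit <- nmf_mu(snips, n_components, seed = seed)
  if (!is.finite(fit$err) || fit$rel_err > max_rel_err)
    stop(sprintf("NMF did not converge (relative error %.3f)", fit$rel_err))
  K <- t(fit$H)                              # P x k kernels
  # remove each kernel's DC floor (inherited from the snippet min-shift);
  # without this the kernels share a large offset, their Gram matrix becomes
  # near-singular and per-flash projections blow up into canceling pairs
  K <- sweep(K, 2, apply(K, 2, min))
  K <- sweep(K, 2, pmax(sqrt(colSums(K^2)), 1e-12), "/")
  tt <- (seq_len(P) - 1) / rate
  on <- tt < protocol$on_s
  colnames(K) <- label_kernels(K, on)
  K <- K[, c("Ltr", "Lsus", "Dtr", "Dsus"), drop = FALSE]
  structure(list(kernels = K, rate_hz = rate, on_s = protocol$on_s,
                 off_s = protocol$off_s, time_s = tt),
            class = "temporal_basis")
}

# label 4 non-negative kernels: the two with most On-window mass are light,
# the others dark; within each pair, the more peaked (higher peak over
# late-window plateau) is transient
label_kernels <- function(K, on) {
  stopifnot(ncol(K) == 4)
  light_frac <- colSums(K[on, , drop = FALSE]) /
    pmax(colSums(K), 1e-12)
  is_light <- rank(-light_frac, ties.method = "first") <= 2
  transiency <- vapply(seq_len(4), function(j) {
    win <- if (is_light[j]) which(on) else which(!on)
    late <- win[win > win[1] + floor(length(win) / 2)]
    max(K[win, j]) / (mean(K[late, j]) + 1e-9)
  }, numeric(1))
  lab <- character(4)
  for (grp in list(which(is_light), which(!is_light))) {
    tr_j <- grp[which.max(transiency[grp])]
    su_j <- setdiff(grp, tr_j)
    pref <- if (all(is_light[grp])) "L" else "D"
    lab[tr_j] <- paste0(pref, "tr")
    lab[su_j] <- paste0(pref, "sus")
  }
  lab
}
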