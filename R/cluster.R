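# PCA reduction and Gaussian-mixture clustering -------------------------------

#' PCA-reduce trial-averaged traces
#'
#' Projects traces onto their first `n_pc` principal components and discards
#' components that near-exclusively carry high-frequency content (a PC is
#' dropped when more than `hf_frac` of the spectral power of its loading
#' vector lies above `hf_cutoff_hz`).
#'
#' @param traces matrix, one row per trace (ROI), columns = time samples.
#' @param n_pc number of leading PCs to consider, default 48.
#' @param rate sampling rate of the traces (Hz), default 42.
#' @param hf_cutoff_hz,hf_frac high-frequency discard rule, defaults 2 Hz
#'   and 0.6.
#' @param discard_hf set FALSE to keep all `n_pc` components.
#' @return List with `scores` (n x kept matrix), `kept_pc_indices`,
#'   `rotation`, `center`, `sdev`, `var_explained_pct` (variance captured by
#'   the first `n_pc` PCs).
#' @export
pca_reduce <- function(traces, n_pc = 48, rate = 42, hf_cutoff_hz = 2,
                       hf_frac = 0.6, discard_hf = TRUE) {
  traces <- as.matrix(traces)
  if (nrow(traces) < n_pc)
    stop("need at least n_pc traces")
  if (n_pc > ncol(traces)) stop("n_pc exceeds trace length")
  pr <- stats::prcomp(traces, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pr$rotation))
  kept <- seq_len(n_pc)
  if (discard_hf) {
    T_ <- ncol(traces)
    freq <- (seq_len(T_) - 1) * rate / T_
    freq <- pmin(freq, rate - freq)          # fold to one-sided
    hf <- freq > hf_cutoff_hz
    frac_hf <- vapply(kept, function(j) {
      pw <- Mod(stats::fft(pr$rotation[, j]))^2
      sum(pw[hf]) / sum(pw)
    }, numeric(1))
    kept <- kept[frac_hf <= hf_frac]
  }
  list(scores = pr$x[, kept, drop = FALSE],
       kept_pc_indices = kept,
       rotation = pr$rotation,
       center = pr$center,
       sdev = pr$sdev,
       var_explained_pct = 100 * sum(pr$sdev[seq_len(n_pc)]^2) /
         sum(pr$sdev^2))
}

# multivariate normal log-density via Cholesky; x: n x d
mvn_logdens <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# single EM run for a Gaussian mixture with full covariances
gmm_em <- function(X, k, max_iter = 200, tol = 1e-6, reg = 1e-6,
                   init_labels = NULL) {
  n <- nrow(X); d <- ncol(X)
  if (is.null(init_labels)) {
    init_labels <- if (k == 1) rep(1L, n)
    else stats::kmeans(X, k, iter.max = 100, nstart = 10)$cluster
  }
  ridge <- diag(reg, d)
  pi_k <- tabulate(init_labels, k) / n
  mu <- t(vapply(seq_len(k), function(j)
    colMeans(X[init_labels == j, , drop = FALSE]), numeric(d)))
  mu <- matrix(mu, k, d)
  sig <- lapply(seq_len(k), function(j) {
    Xi <- X[init_labels == j, , drop = FALSE]
    if (nrow(Xi) > d) stats::cov(Xi) + ridge else diag(apply(X, 2, stats::var)) + ridge
  })
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logp <- vapply(seq_len(k), function(j)
      log(pmax(pi_k[j], 1e-300)) + mvn_logdens(X, mu[j, ], sig[[j]]),
      numeric(n))
    logp <- matrix(logp, n, k)
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    resp <- exp(logp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {                     # re-seed empty component
      j0 <- which.min(nk)
      far <- which.min(lse)
      resp[far, ] <- 0; resp[far, j0] <- 1
      nk <- colSums(resp)
    }
    pi_k <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu[j, ])
      sig[[j]] <- crossprod(Xc * sqrt(resp[, j])) / nk[j] + ridge
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  labels <- max.col(resp)
  list(loglik = ll, labels = labels, means = mu, covs = sig, weights = pi_k)
}

#' Fit Gaussian mixtures over a range of cluster counts, selecting by BIC
#'
#' Full-covariance Gaussian mixture models fitted by EM with `n_init`
#' k-means-initialized restarts per candidate `k`; the model minimizing the
#' Bayesian information criterion is returned together with the BIC curve.
#' Singular covariances are handled by a small ridge regularization.
#'
#' @param scores numeric matrix (observations x dimensions), e.g. from
#'   [pca_reduce()].
#' @param k_range candidate cluster counts, default 1:40.
#' @param n_init EM restarts per k, default 10.
#' @param seed RNG seed (restarts and k-means init).
#' @param reg covariance ridge.
#' @return An object of class `gmm_model`: `labels`, `n_clusters`, `means`,
#'   `covs`, `weights`, `loglik`, `bic_curve` (named numeric), `seed`.
#' @export
fit_gmm_bic <- function(scores, k_range = 1:40, n_init = 10, seed = 1,
                        reg = 1e-6) {
  X <- as.matrix(scores)
  stopifnot(length(k_range) >= 1)
  n <- nrow(X); d <- ncol(X)
  bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  best_all <- NULL
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    if (k > n) next
    best <- NULL
    for (ri in seq_len(n_init)) {
      set.seed(seed + 1000 * ki + ri)
      fit <- tryCatch(gmm_em(X, k, reg = reg), error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
      if (k == 1) break                       # deterministic
    }
    if (is.null(best)) next
    p <- (k - 1) + k * d + k * d * (d + 1) / 2
    bic[ki] <- -2 * best$loglik + p * log(n)
    if (is.null(best_all) || bic[ki] < best_all$bic)
      best_all <- c(best, list(bic = bic[ki], k = k))
  }
  if (is.null(best_all)) stop("no GMM could be fitted")
  structure(list(labels = best_all$labels, n_clusters = best_all$k,
                 means = best_all$means, covs = best_all$covs,
                 weights = best_all$weights, loglik = best_all$loglik,
                 bic_curve = bic, seed = seed), class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat("Gaussian mixture model:", x$n_clusters, "clusters (BIC-selected)\n")
  invisible(x)
}

#' Adjusted Rand index between two labelings
#' @param a,b integer/factor label vectors of equal length.
#' @return Scalar ARI (1 = identical partitions up to relabeling).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Summarize clusters: mean traces, IPL and region histograms
#'
#' Re-orders clusters by their mean IPL depth (ascending from the
#' inner-nuclear-layer border), computes per-cluster mean traces,
#' area-normalized IPL-depth histograms (per cluster) and region histograms
#' normalized within each region. Empty clusters are dropped with a warning.
#'
#' @param labels integer cluster labels (e.g. from [fit_gmm_bic()]).
#' @param traces matrix of traces (rows aligned with `labels`).
#' @param depths IPL depths in \[0,1\], aligned with `labels`.
#' @param regions optional region factor (AZ/D/N/V).
#' @param depth_breaks histogram breaks for IPL depth.
#' @return List with `labels` (re-ordered), `n_clusters`, `cluster_means`
#'   (k x T), `cluster_ipl_mean`, `ipl_hist` (density matrix, bins x k),
#'   `region_hist` (regions x k, normalized per region), `n_rois` (per
#'   cluster), `order` (old -> new mapping).
#' @export
summarize_clusters <- function(labels, traces, depths, regions = NULL,
                               depth_breaks = seq(0, 1, by = 0.1)) {
  if (inherits(labels, "gmm_model")) labels <- labels$labels
  traces <- as.matrix(traces)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(traces), length(depths) == length(labels))
  ks <- seq_len(max(labels))
  sizes <- vapply(ks, function(k) sum(labels == k), integer(1))
  if (any(sizes == 0)) warning("empty cluster excluded")
  ks <- ks[sizes > 0]
  depth_mean <- vapply(ks, function(k) mean(depths[labels == k]), numeric(1))
  ord <- order(depth_mean)
  new_labels <- match(labels, ks[ord])
  k_n <- length(ks)
  means <- t(vapply(seq_len(k_n), function(j)
    colMeans(traces[new_labels == j, , drop = FALSE]), numeric(ncol(traces))))
  ipl_hist <- vapply(seq_len(k_n), function(j) {
    h <- graphics::hist(depths[new_labels == j], breaks = depth_breaks,
                        plot = FALSE)
    h$density
  }, numeric(length(depth_breaks) - 1))
  region_hist <- NULL
  if (!is.null(regions)) {
    tab <- table(regions, new_labels)
    region_hist <- sweep(tab, 1, pmax(rowSums(tab), 1), "/")
  }
  list(labels = new_labels, n_clusters = k_n, cluster_means = means,
       cluster_ipl_mean = sort(depth_mean),
       ipl_hist = ipl_hist, region_hist = region_hist,
       n_rois = vapply(seq_len(k_n), function(j) sum(new_labels == j),
                       integer(1)),
       order = ord)
}
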