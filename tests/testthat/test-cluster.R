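# cluster module: PCA reduction, GMM + BIC, cluster summaries

test_that("pca_reduce concentrates variance and reconstructs exactly", {
  set.seed(21)
  patterns <- matrix(rnorm(3 * 200), 3, 200)
  mix <- matrix(runif(60 * 3), 60, 3)
  traces <- mix %*% patterns + matrix(rnorm(60 * 200, 0, 1e-3), 60, 200)
  red <- pca_reduce(traces, n_pc = 10, discard_hf = FALSE)
  varfrac <- sum(red$sdev[1:3]^2) / sum(red$sdev^2)
  expect_gt(varfrac, 0.95)
  # orthonormal reconstruction from all PCs reproduces the centered traces
  full <- pca_reduce(traces, n_pc = min(dim(traces)), discard_hf = FALSE)
  scores_all <- sweep(traces, 2, full$center) %*% full$rotation
  back <- scores_all %*% t(full$rotation)
  expect_equal(back, sweep(traces, 2, full$center), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("pca_reduce discards high-frequency components", {
  set.seed(22)
  T_ <- 420; rate <- 42
  tt <- (seq_len(T_) - 1) / rate
  slow <- sin(2 * pi * 0.4 * tt)
  fast <- sin(2 * pi * 8 * tt)              # > 2 Hz
  traces <- rbind(
    t(replicate(30, slow * rnorm(1, 1, 0.2))),
    t(replicate(30, fast * rnorm(1, 1, 0.2))))
  traces <- traces + matrix(rnorm(60 * T_, 0, 1e-3), 60)
  red <- pca_reduce(traces, n_pc = 4, rate = rate)
  # the PC carrying the 8 Hz pattern is discarded
  hf_pc_scores <- abs(cor(sweep(traces, 2, colMeans(traces)) %*%
                            red$rotation[, 1:4], traces %*% fast))
  kept_rot <- red$rotation[, red$kept_pc_indices, drop = FALSE]
  frac_hf_kept <- vapply(seq_len(ncol(kept_rot)), function(j) {
    pw <- Mod(fft(kept_rot[, j]))^2
    freq <- pmin((seq_len(T_) - 1) * rate / T_,
                 rate - (seq_len(T_) - 1) * rate / T_)
    sum(pw[freq > 2]) / sum(pw)
  }, numeric(1))
  expect_true(all(frac_hf_kept <= 0.6))
  expect_lt(length(red$kept_pc_indices), 4)
  expect_error(pca_reduce(traces[1:3, ], n_pc = 10), "n_pc")
})

test_that("fit_gmm_bic finds separable blob structure (k and ARI)", {
  set.seed(23)
  ctrs <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, byrow = TRUE)
  lab <- sample(1:3, 300, TRUE)
  X <- ctrs[lab, ] + matrix(rnorm(900, 0, 0.1), 300)
  m <- fit_gmm_bic(X, k_range = 1:6, n_init = 5, seed = 1)
  expect_equal(m$n_clusters, 3L)
  expect_equal(adjusted_rand_index(m$labels, lab), 1)
  expect_equal(sum(!is.na(m$bic_curve)), 6L)
  # single blob -> k = 1
  X1 <- matrix(rnorm(400, 0, 0.5), 200, 2)
  expect_equal(fit_gmm_bic(X1, k_range = 1:4, n_init = 3,
                           seed = 1)$n_clusters, 1L)
})

test_that("gmm clustering is reproducible under a fixed seed", {
  set.seed(24)
  X <- rbind(matrix(rnorm(200, 0, 1), 100, 2),
             matrix(rnorm(200, 6, 1), 100, 2))
  m1 <- fit_gmm_bic(X, k_range = 1:3, n_init = 4, seed = 9)
  m2 <- fit_gmm_bic(X, k_range = 1:3, n_init = 4, seed = 9)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$bic_curve, m2$bic_curve)
})

test_that("summarize_clusters orders by IPL depth and normalizes histograms", {
  set.seed(25)
  n <- 90
  lab <- rep(1:3, each = 30)
  # archetype 2 shallow, 3 mid, 1 deep: summary must re-order as 2, 3, 1
  depths <- c(runif(30, 0.7, 0.9), runif(30, 0.05, 0.25),
              runif(30, 0.4, 0.6))
  traces <- matrix(rnorm(n * 50), n) + lab * 3
  regions <- factor(sample(c("AZ", "D", "N", "V"), n, TRUE))
  s <- summarize_clusters(lab, traces, depths, regions)
  expect_equal(s$n_clusters, 3L)
  expect_true(!is.unsorted(s$cluster_ipl_mean))
  expect_equal(s$labels[1], 3L)           # old cluster 1 is deepest -> last
  expect_equal(s$labels[31], 1L)          # old cluster 2 shallowest -> first
  # IPL histograms are densities: area integrates to 1 per cluster
  binw <- 0.1
  expect_equal(unname(colSums(s$ipl_hist) * binw), rep(1, 3),
               tolerance = 1e-9)
  # region histograms normalized within each region
  expect_equal(unname(rowSums(s$region_hist)), rep(1, 4), tolerance = 1e-9)
  # uniform depths in a single cluster: flat density
  s1 <- summarize_clusters(rep(1, 500), matrix(rnorm(500 * 10), 500),
                           runif(500))
  expect_lt(diff(range(s1$ipl_hist)), 0.6)
  # a label value with no members is excluded with a warning
  expect_warning(summarize_clusters(c(rep(1, 10), rep(3, 10)),
                                    matrix(rnorm(20 * 5), 20),
                                    runif(20)), "empty cluster")
})

test_that("cluster labels permutation leaves the set of cluster means
          unchanged", {
  set.seed(26)
  lab <- rep(1:3, each = 20)
  traces <- matrix(rnorm(60 * 30), 60) + lab
  depths <- runif(60)
  s1 <- summarize_clusters(lab, traces, depths)
  perm <- c(2L, 3L, 1L)[lab]
  s2 <- summarize_clusters(perm, traces, depths)
  m1 <- s1$cluster_means[order(s1$cluster_means[, 1]), ]
  m2 <- s2$cluster_means[order(s2$cluster_means[, 1]), ]
  expect_equal(m1, m2)
})

test_that("BIC-selected k matches the archetype count on synthetic
          populations (W = 3 and 6 separable archetypes)", {
  # traces from well-separated weight archetypes (equal abundance so every
  # component can support a full covariance), clustered end-to-end
  eq <- rep(1 / 6, 6)
  names(eq) <- names(spectral_archetypes())
  pop <- make_population(n_rois = 240, proportions = eq, noise_sd = 0.02,
                         n_repeats = 5, weight_jitter = 0.05, seed = 31)
  recs <- simulate_roi_traces(pop, default_protocol(), default_cones(),
                              default_basis())
  traces <- t(vapply(recs, function(r) rowMeans(r$repeats),
                     numeric(nrow(recs[[1]]$repeats))))
  red <- pca_reduce(traces, n_pc = 8, rate = 42)
  truth_k <- length(unique(pop$archetype))
  m <- fit_gmm_bic(red$scores[, 1:5], k_range = 1:9, n_init = 4, seed = 2)
  expect_equal(m$n_clusters, truth_k)
  expect_gt(adjusted_rand_index(m$labels, as.integer(pop$archetype)), 0.99)
})
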