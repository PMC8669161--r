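# decompose module: NMF basis, flash decomposition, lasso cone weights,
# normalization, reconstruction

test_that("lasso coordinate descent agrees with glmnet (independent oracle)
          and shrinks monotonically", {
  skip_if_not_installed("glmnet")
  set.seed(41)
  n <- 120; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1.5, -0.8, 0, 0.3)
  y <- X %*% beta + rnorm(n, 0, 0.2)
  for (lam in c(0.5, 5, 50)) {
    b_cd <- lasso_cd(X, y, lam)
    # glmnet objective: 1/(2n)||y-Xb||^2 + lambda_g ||b||_1
    b_gl <- as.numeric(glmnet::glmnet(X, y, lambda = lam / (2 * n),
                                      intercept = FALSE,
                                      standardize = FALSE,
                                      thresh = 1e-14)$beta)
    expect_equal(unname(b_cd), b_gl, tolerance = 1e-4)
  }
  # shrinkage monotonicity: sum |b| non-increasing in lambda
  lams <- c(0, 1, 5, 20, 100, 500)
  l1 <- vapply(lams, function(l) sum(abs(lasso_cd(X, y, l))), numeric(1))
  expect_true(all(diff(l1) <= 1e-10))
})

test_that("NMF extracts the four temporal kernels from noiseless snippets", {
  protocol <- default_protocol(); basis <- default_basis()
  set.seed(42)
  coefs <- matrix(rexp(130 * 4)^1.5, 130, 4)
  V <- coefs %*% t(basis$kernels)
  traces <- matrix(as.vector(t(V)), nrow = 10, byrow = TRUE)
  bhat <- extract_temporal_basis_nmf(traces, protocol, seed = 3)
  expect_equal(ncol(bhat$kernels), 4L)
  expect_true(all(bhat$kernels >= 0))
  expect_equal(colnames(bhat$kernels), c("Ltr", "Lsus", "Dtr", "Dsus"))
  # each true kernel correlates > 0.95 with its matched estimate
  expect_true(all(diag(cor(basis$kernels, bhat$kernels)) > 0.95))
  expect_error(extract_temporal_basis_nmf(matrix(0, 5, 1638), protocol),
               "all-zero")
})

test_that("decompose_response projects flash snippets onto the kernels", {
  protocol <- default_protocol(); basis <- default_basis()
  P <- nrow(basis$kernels)
  # trace that is 1.0 x Lsus at every flash
  tr <- rep(basis$kernels[, "Lsus"], protocol$n_leds)
  dec <- decompose_response(tr, basis, protocol)
  expect_equal(dim(dec$coeffs), c(4L, 10L))
  expect_equal(unname(dec$coeffs["Lsus", ]), rep(1, 10), tolerance = 1e-9)
  expect_equal(max(abs(dec$coeffs[c("Ltr", "Dtr", "Dsus"), ])), 0,
               tolerance = 1e-9)
  # zero trace -> all-zero array
  dec0 <- decompose_response(rep(0, P * 13), basis, protocol)
  expect_equal(max(abs(dec0$coeffs)), 0)
  # collinear kernels -> conditioning error
  bad <- basis; bad$kernels[, 2] <- bad$kernels[, 1] * (1 + 1e-12)
  expect_error(decompose_response(tr, bad, protocol), "conditioning")
})

test_that("decomposition coefficients match the forward model
          (coeffs[k, led] = sum_c a[c,k] S_c)", {
  protocol <- default_protocol(); cones <- default_cones()
  basis <- default_basis()
  set.seed(43)
  W <- rand_weights()
  sig <- forward_trace(W)
  dec <- decompose_response(sig, basis, protocol)
  S <- spectramap:::eval_cone_tunings(
    cones, protocol$led_peaks_nm[protocol$central_led_indices])
  pred <- t(S %*% spectramap:::weights_to_raw(W))
  expect_gt(cor(as.vector(dec$coeffs), as.vector(pred)), 0.99)
})

test_that("interpolate_tuning passes through nodes, averages midpoints and
          extrapolates flat", {
  peaks <- c(622, 592, 550, 516, 501, 464, 448, 427, 407, 381)
  vals <- rep(2, 10)
  expect_equal(interpolate_tuning(vals, peaks), rep(2, 251))
  set.seed(44)
  v <- rnorm(10)
  cur <- interpolate_tuning(v, peaks, grid = 360:610)
  expect_equal(cur[550 - 359], v[3])                   # node value exact
  mid <- (464 + 448) / 2                               # integer midpoint
  expect_equal(cur[mid - 359], (v[6] + v[7]) / 2)      # linear midpoint
  expect_equal(cur[1], v[10])                          # flat below 381
})

test_that("fit_cone_weights recovers exact cone combinations and returns
          16 weights", {
  cones <- default_cones()
  set.seed(45)
  a_true <- matrix(runif(16, -2, 2), 4, 4)
  tun <- cones$tuning %*% a_true
  fit <- fit_cone_weights(tun, cones, lasso_lambda = 1e-6)
  expect_equal(length(fit$w), 16L)
  expect_equal(unname(fit$w), unname(-a_true), tolerance = 1e-3)
  expect_equal(mean(abs(fit$w_norm)), 1, tolerance = 1e-12)
  # all-zero tunings -> all-zero weights, no error
  fit0 <- fit_cone_weights(matrix(0, 251, 4), cones, lasso_lambda = 1)
  expect_true(all(fit0$w == 0))
  # degenerate cone set -> conditioning error
  broke <- cones; broke$tuning[, "green"] <- broke$tuning[, "red"]
  expect_error(fit_cone_weights(tun, broke, 1e-6), "conditioning")
})

test_that("normalize_weights scales mean |w| to one and is idempotent", {
  set.seed(46)
  W <- rand_weights()
  Wn <- normalize_weights(W)
  expect_equal(mean(abs(Wn)), 1, tolerance = 1e-12)
  expect_equal(normalize_weights(Wn), Wn, tolerance = 1e-12)
  expect_equal(sign(Wn), sign(W))
  # single nonzero entry 4 -> becomes 16 (mean |w| = 4/16)
  W1 <- matrix(0, 4, 4); W1[2, 3] <- 4
  expect_equal(normalize_weights(W1)[2, 3], 16)
  expect_error(normalize_weights(matrix(0, 4, 4)), "all-zero")
})

test_that("round trip: noiseless forward-simulated weights are recovered and
          reconstruction matches the input", {
  protocol <- default_protocol(); cones <- default_cones()
  basis <- default_basis()
  win <- central_window()
  set.seed(47)
  for (i in 1:3) {
    W <- rand_weights()
    sig <- forward_trace(W)
    fit <- decompose_to_weights(sig, basis, protocol, cones,
                                lasso_lambda = 1e-6)
    expect_equal(unname(fit$w), unname(W), tolerance = 1e-3)
    rec <- reconstruct(fit, cones, basis, protocol)
    expect_gt(cor(rec$full, sig[win]), 0.999)
    # per-cone totals and sub-traces sum to the full reconstruction
    expect_equal(colSums(rec$per_cone), rec$full, tolerance = 1e-12)
    expect_equal(apply(rec$sub, 3, sum), rec$full, tolerance = 1e-12)
  }
  # zero weights -> zero reconstruction
  rec0 <- reconstruct(matrix(0, 4, 4,
                             dimnames = dimnames(rand_weights())),
                      cones, basis, protocol)
  expect_equal(max(abs(rec0$full)), 0)
})

test_that("equivariance: scaling the trace scales unnormalized weights,
          normalized weights unchanged", {
  protocol <- default_protocol(); cones <- default_cones()
  basis <- default_basis()
  set.seed(48)
  W <- rand_weights()
  sig <- forward_trace(W)
  f1 <- decompose_to_weights(sig, basis, protocol, cones, 1e-6)
  f2 <- decompose_to_weights(3 * sig, basis, protocol, cones, 3e-6)
  expect_equal(f2$w, 3 * f1$w, tolerance = 1e-6)
  expect_equal(f2$w_norm, f1$w_norm, tolerance = 1e-6)
})

test_that("P1 parameter recovery: 200 noisy ROIs, elementwise r > 0.95", {
  protocol <- default_protocol(); cones <- default_cones()
  basis <- default_basis()
  set.seed(49)
  true_w <- c(); est_w <- c(); abs_err <- c()
  for (i in 1:200) {
    W <- rand_weights()
    sig <- forward_trace(W)
    noisy <- sig + rnorm(length(sig), 0, 0.1 * sd(sig))
    fit <- decompose_to_weights(noisy, basis, protocol, cones,
                                lasso_lambda = 1e-6)
    true_w <- c(true_w, as.vector(W))
    est_w <- c(est_w, as.vector(fit$w))
    abs_err <- c(abs_err, abs(as.vector(fit$w) - as.vector(W)))
  }
  expect_gt(cor(true_w, est_w), 0.95)
  # report-style check on the median absolute error
  expect_lt(median(abs_err), 0.5)
})
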