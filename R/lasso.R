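# Lasso regression (coordinate descent) ---------------------------------------

#' Lasso regression by coordinate descent
#'
#' Solves `argmin_b ||y - X b||^2 + lambda * ||b||_1` (no intercept, no
#' standardization). Designed for the small, well-conditioned spectral
#' unmixing problems of this package (p = 4 cone regressors), where exact
#' control of the objective matters more than speed.
#'
#' @param X design matrix (n x p).
#' @param y response vector (length n).
#' @param lambda non-negative L1 penalty on the `||.||^2 + lambda ||.||_1`
#'   scale.
#' @param max_iter,tol iteration cap and coordinate-update convergence
#'   tolerance.
#' @return Coefficient vector (length p, named by `colnames(X)`).
#' @export
lasso_cd <- function(X, y, lambda, max_iter = 10000, tol = 1e-12) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), lambda >= 0)
  p <- ncol(X)
  xx <- colSums(X^2)
  if (any(xx == 0)) stop("zero-variance regressor")
  b <- rep(0, p)
  r <- y
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- b[j]
      rho <- sum(X[, j] * r) + xx[j] * bj_old
      b[j] <- soft(rho, lambda / 2) / xx[j]
      if (b[j] != bj_old) {
        r <- r - X[, j] * (b[j] - bj_old)
        delta <- max(delta, abs(b[j] - bj_old))
      }
    }
    if (delta < tol) break
  }
  names(b) <- colnames(X)
  b
}

# k-fold cross-validation for the lasso penalty, fitted jointly over several
# response vectors (columns of Y); returns the lambda with minimal mean CV
# squared error
cv_lasso_lambda <- function(X, Y, lambdas = NULL, nfolds = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (is.null(lambdas)) {
    lmax <- max(abs(crossprod(X, Y))) * 2
    lambdas <- lmax * 10^seq(-6, 0, length.out = 20)
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(nfolds), length.out = n))
  err <- matrix(0, length(lambdas), ncol(Y))
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    for (li in seq_along(lambdas)) for (k in seq_len(ncol(Y))) {
      b <- lasso_cd(X[tr, , drop = FALSE], Y[tr, k],
                    lambdas[li] * mean(tr))  # scale penalty with fold size
      err[li, k] <- err[li, k] +
        sum((Y[!tr, k] - X[!tr, , drop = FALSE] %*% b)^2)
    }
  }
  lambdas[which.min(rowSums(err))]
}
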