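#' Radial basis function kernel
#'
#' The six kernel families used for interpolating reduced coordinates over
#' the pose space, as functions of the Euclidean distance `r` and the shape
#' parameter `a` (smaller `a` = flatter kernel):
#' \describe{
#'   \item{G}{Gaussian `exp(-(a r)^2)`}
#'   \item{MQ}{multiquadric `sqrt(1 + (a r)^2)` (only conditionally
#'     positive definite; use augmented fits)}
#'   \item{IMQ}{inverse multiquadric `1 / sqrt(1 + (a r)^2)`}
#'   \item{MC0}{Matern C0 `exp(-a r)`}
#'   \item{MC2}{Matern C2 `exp(-a r) (1 + a r)`}
#'   \item{MC4}{Matern C4 `exp(-a r) (3 + 3 a r + (a r)^2)`}
#' }
#'
#' @param family one of `"G"`, `"MQ"`, `"IMQ"`, `"MC0"`, `"MC2"`, `"MC4"`.
#' @param a shape parameter (> 0, finite).
#' @return an object of class `rbf_kernel`.
#' @export
rbf_kernel <- function(family = c("MC0", "G", "MQ", "IMQ", "MC2", "MC4"),
                       a = 1e-4) {
  family <- match.arg(family)
  if (!is.finite(a) || a <= 0) stop("shape parameter a must be finite and > 0")
  structure(list(family = family, a = a,
                 strictly_pd = family != "MQ"),
            class = "rbf_kernel")
}

#' Evaluate an RBF kernel at distances
#'
#' @param kernel an [rbf_kernel()].
#' @param r nonnegative distances (vector or matrix).
#' @return kernel values, same shape as `r`.
#' @export
kernel_eval <- function(kernel, r) {
  if (any(r < 0)) stop("distances must be nonnegative")
  ar <- kernel$a * r
  switch(kernel$family,
         G = exp(-ar^2),
         MQ = sqrt(1 + ar^2),
         IMQ = 1 / sqrt(1 + ar^2),
         MC0 = exp(-ar),
         MC2 = exp(-ar) * (1 + ar),
         MC4 = exp(-ar) * (3 + 3 * ar + ar^2))
}

#' Min-max normalisation of pose parameters
#'
#' Affinely maps every parameter dimension onto \[0, 1\] using the training
#' bounds, so that the Euclidean distances entering the kernels are free of
#' the differing raw scales (mm vs degrees).
#'
#' @param P n_p x n_s parameter matrix (poses as columns) or a length-n_p
#'   vector.
#' @param bounds 2 x n_p matrix with rows `lower` and `upper`.
#' @return normalised matrix/vector of the same shape.
#' @export
normalize_params <- function(P, bounds) {
  vec <- is.null(dim(P))
  P <- cbind(P)
  lo <- bounds[1, ]; hi <- bounds[2, ]
  if (any(hi <= lo))
    stop("degenerate parameter dimension (lower >= upper): ",
         "remove the constant parameter from the plan")
  if (nrow(P) != length(lo)) stop("parameter count does not match bounds")
  out <- (P - lo) / (hi - lo)
  if (vec) as.numeric(out) else out
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(P, bounds) {
  vec <- is.null(dim(P))
  P <- cbind(P)
  out <- P * (bounds[2, ] - bounds[1, ]) + bounds[1, ]
  if (vec) as.numeric(out) else out
}

#' Fit an RBF interpolant to reduced snapshot coordinates
#'
#' Plain fit: solve `S_r = A B` with `B_ij = phi(||mu_i - mu_j||)` over the
#' normalised training poses. Augmented fit: append a degree-1 polynomial
#' tail `h(mu) = eta . (1, mu_1, ..., mu_np)` and the side conditions that
#' the RBF coefficients be orthogonal to the polynomials, solving the
#' saddle-point block system. Augmentation is required for the
#' conditionally positive definite MQ kernel and improves reproduction for
#' the rest.
#'
#' @param S_r n x n_s reduced coordinates (one column per training pose).
#' @param P n_p x n_s training pose matrix (raw units).
#' @param kernel an [rbf_kernel()].
#' @param bounds 2 x n_p normalisation bounds (rows lower/upper).
#' @param augmented add the linear polynomial tail (default TRUE).
#' @param cond_warn reciprocal-condition threshold below which an
#'   ill-conditioning warning is emitted.
#' @return an object of class `rbf_interpolant`.
#' @export
fit_rbf <- function(S_r, P, kernel, bounds, augmented = TRUE,
                    cond_warn = 1e-13) {
  S_r <- rbind(S_r)
  P <- cbind(P)
  n_s <- ncol(P)
  if (ncol(S_r) != n_s) stop("S_r and P must have the same number of columns")
  Ph <- normalize_params(P, bounds)
  Dm <- as.matrix(stats::dist(t(Ph)))
  if (any(Dm[upper.tri(Dm)] < 1e-12))
    stop("duplicate training poses after normalisation")
  if (kernel$family == "MQ" && !augmented)
    warning("MQ kernel is only conditionally positive definite; ",
            "augmentation is recommended")
  B <- kernel_eval(kernel, Dm)
  n_p <- nrow(P)
  if (augmented) {
    if (n_s <= n_p + 1L)
      stop("augmented fit needs more training poses than polynomial terms")
    Q <- cbind(1, t(Ph))                      # n_s x (n_p + 1)
    M <- rbind(cbind(B, Q),
               cbind(t(Q), matrix(0, n_p + 1L, n_p + 1L)))
    rhs <- rbind(t(S_r), matrix(0, n_p + 1L, nrow(S_r)))
    rc <- rcond(M)
    if (rc < cond_warn)
      warning("augmented RBF system is ill-conditioned (rcond = ",
              signif(rc, 3), "); consider a larger shape parameter")
    X <- solve(M, rhs)
    A <- t(X[seq_len(n_s), , drop = FALSE])
    eta <- t(X[n_s + seq_len(n_p + 1L), , drop = FALSE])
  } else {
    rc <- rcond(B)
    if (rc < cond_warn)
      warning("RBF interpolation matrix is ill-conditioned (rcond = ",
              signif(rc, 3), "); consider a larger shape parameter")
    A <- t(solve(B, t(S_r)))                  # A = S_r B^{-1} (B symmetric)
    eta <- NULL
  }
  structure(list(kernel = kernel, centers = Ph, A = A, eta = eta,
                 bounds = bounds, augmented = augmented, n_out = nrow(S_r)),
            class = "rbf_interpolant")
}

#' @export
print.rbf_interpolant <- function(x, ...) {
  cat(sprintf("rbf_interpolant: %s(a = %g), %s, %d centers, %d outputs\n",
              x$kernel$family, x$kernel$a,
              if (x$augmented) "augmented" else "plain",
              ncol(x$centers), x$n_out))
  invisible(x)
}

#' Interpolated reduced weights at a pose
#'
#' `w(mu) = sum_i omega_i phi(||mu_hat - mu_hat_i||) (+ h(mu_hat))`. A
#' warning is emitted when the pose lies outside the normalisation bounds
#' (extrapolation).
#'
#' @param interp an [fit_rbf()] result.
#' @param pose raw pose vector (length n_p).
#' @return numeric weight vector of length `n` (the reduced dimension).
#' @export
predict_weights <- function(interp, pose) {
  pose <- as.numeric(pose)
  mu <- normalize_params(pose, interp$bounds)
  if (any(mu < -1e-9 | mu > 1 + 1e-9))
    warning("pose outside the training bounds: extrapolating")
  r <- sqrt(colSums((interp$centers - mu)^2))
  w <- as.numeric(interp$A %*% kernel_eval(interp$kernel, r))
  if (interp$augmented)
    w <- w + as.numeric(interp$eta %*% c(1, mu))
  w
}

#' Shape-parameter and kernel-family sweep
#'
#' Fits an interpolant for every (family, shape parameter, augmentation)
#' cell on the training poses, measures the mean absolute error of the
#' reconstructed fields against held-out high-fidelity fields, and selects
#' the cell with the smallest error (ties broken towards the smaller shape
#' parameter). Singular fits are recorded as failed cells (`NA`) rather
#' than aborting the sweep.
#'
#' @param basis a [compute_pod()] result used to reconstruct fields.
#' @param S_r_train n x n_train reduced training coordinates.
#' @param P_train n_p x n_train training poses.
#' @param S_holdout N x n_test held-out full fields.
#' @param P_holdout n_p x n_test held-out poses.
#' @param bounds normalisation bounds.
#' @param families kernel families to try.
#' @param a_grid shape-parameter grid.
#' @param augmented logical values to try (default both).
#' @return data frame `(family, a, augmented, mae)` with the selected cell
#'   in attribute `selected`.
#' @export
shape_parameter_sweep <- function(basis, S_r_train, P_train,
                                  S_holdout, P_holdout, bounds,
                                  families = c("G", "MQ", "IMQ", "MC0", "MC2", "MC4"),
                                  a_grid = 10^seq(-4, 1, by = 1),
                                  augmented = c(FALSE, TRUE)) {
  cells <- expand.grid(family = families, a = a_grid, augmented = augmented,
                       stringsAsFactors = FALSE)
  cells$mae <- vapply(seq_len(nrow(cells)), function(i) {
    fit <- tryCatch(
      suppressWarnings(fit_rbf(S_r_train, P_train,
                               rbf_kernel(cells$family[i], cells$a[i]),
                               bounds, augmented = cells$augmented[i])),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    errs <- vapply(seq_len(ncol(P_holdout)), function(j) {
      w <- suppressWarnings(predict_weights(fit, P_holdout[, j]))
      evaluate_mae(pod_reconstruct(basis, w), S_holdout[, j])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  ok <- which(is.finite(cells$mae))
  if (!length(ok)) stop("every sweep cell failed to fit")
  best <- ok[order(cells$mae[ok], cells$a[ok])][1]
  attr(cells, "selected") <- cells[best, , drop = FALSE]
  cells
}
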