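#' Proper orthogonal decomposition of a snapshot matrix
#'
#' Thin SVD `S = U Sigma Z^T` of the snapshot matrix followed by
#' energy-based truncation: the retained mode count `n` is the smallest
#' count whose captured squared-singular-value fraction strictly exceeds
#' the tolerance `kappa`. Mode signs are fixed deterministically so that
#' each mode's largest-magnitude entry is positive.
#'
#' @param S numeric N x n_s snapshot matrix (one field per column).
#' @param kappa energy tolerance in (0, 1], default 0.9999 (99.99%).
#' @return an object of class `pod_basis`: list with the truncated modes
#'   `V` (N x n), the full singular-value vector `sv`, `n`, `kappa`, and
#'   the cumulative energy fractions `energy`.
#' @export
compute_pod <- function(S, kappa = 0.9999) {
  S <- as.matrix(S)
  if (any(!is.finite(S))) stop("snapshot matrix contains non-finite entries")
  if (ncol(S) < 2L) stop("at least 2 snapshots are required")
  if (all(S == 0)) stop("all-zero snapshot matrix")
  if (kappa <= 0 || kappa > 1) stop("kappa must lie in (0, 1]")
  dec <- svd(S, nu = min(dim(S)), nv = 0)
  sv <- dec$d
  energy <- cumsum(sv^2) / sum(sv^2)
  n <- which(energy > kappa)[1]
  if (is.na(n)) n <- length(sv)  # kappa = 1 with rounding: keep everything
  V <- dec$u[, seq_len(n), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(n)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(V = V, sv = sv, n = n, kappa = kappa, energy = energy),
            class = "pod_basis")
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf(
    "pod_basis: %d of %d modes retained (energy %.6f > kappa = %g), trunc. error %.3g\n",
    x$n, length(x$sv), x$energy[x$n], x$kappa, truncation_error(x$sv, x$n)))
  invisible(x)
}

#' Relative truncation error of a POD basis
#'
#' Relative tail energy `eps(n) = sqrt(sum_{i>n} sv_i^2 / sum_i sv_i^2)`,
#' which equals the relative Frobenius error of reconstructing the
#' snapshot matrix from its leading `n` modes. Zero at full rank and
#' non-increasing in `n`.
#'
#' @param sv singular values (descending) or a [compute_pod()] result.
#' @param n number of retained modes (1 <= n <= length(sv)).
#' @return scalar relative error.
#' @export
truncation_error <- function(sv, n) {
  if (inherits(sv, "pod_basis")) sv <- sv$sv
  if (n < 1 || n > length(sv)) stop("n out of range")
  if (n == length(sv)) return(0)
  sqrt(sum(sv[(n + 1):length(sv)]^2) / sum(sv^2))
}

#' Project snapshots onto the reduced basis
#'
#' `S_r = V^T S` (n x n_s reduced coordinates).
#'
#' @param basis a [compute_pod()] result (or an N x n mode matrix).
#' @param S N x n_s field matrix.
#' @return n x n_s reduced snapshot matrix.
#' @export
pod_reduce <- function(basis, S) {
  V <- if (inherits(basis, "pod_basis")) basis$V else basis
  crossprod(V, S)
}

#' Reconstruct a full field from reduced coordinates
#'
#' `phi = V w`, linear in the weights.
#'
#' @param basis a [compute_pod()] result (or mode matrix).
#' @param w length-n weight vector or n x m weight matrix.
#' @return full field vector (or N x m matrix).
#' @export
pod_reconstruct <- function(basis, w) {
  V <- if (inherits(basis, "pod_basis")) basis$V else basis
  out <- V %*% w
  if (NCOL(out) == 1L) as.numeric(out) else out
}

#' Energy-decay plot of a POD basis
#'
#' @param x a [compute_pod()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pod_basis <- function(x, ...) {
  graphics::plot(seq_along(x$sv), x$sv^2 / sum(x$sv^2), log = "y",
                 xlab = "mode", ylab = "relative energy", type = "b", ...)
  graphics::abline(v = x$n + 0.5, lty = 2)
  invisible(x)
}
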