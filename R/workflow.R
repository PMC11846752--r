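#' Sampling plan over the pose space
#'
#' Either an equidistant tensor grid (`points` per dimension, endpoints
#' included; a dimension with a single point is frozen at the interval
#' midpoint) or a seeded pseudorandom plan of `n` uniform draws within the
#' bounds.
#'
#' @param mode `"grid"` or `"pseudorandom"`.
#' @param bounds 2 x n_p matrix of pose bounds (rows lower/upper).
#' @param points grid mode: points per dimension, scalar or length n_p.
#' @param n pseudorandom mode: number of samples.
#' @param seed pseudorandom mode: integer RNG seed.
#' @return an object of class `sampling_plan`.
#' @export
sampling_plan <- function(mode = c("grid", "pseudorandom"), bounds,
                          points = 3L, n = 20L, seed = 1L) {
  mode <- match.arg(mode)
  if (any(!is.finite(bounds))) stop("pose bounds must be finite")
  n_p <- ncol(bounds)
  points <- rep_len(as.integer(points), n_p)
  if (mode == "grid" && any(points < 1L))
    stop("grid mode needs at least 1 point per dimension")
  structure(list(mode = mode, bounds = bounds, points = points,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Equidistant training grid
#'
#' Full tensor grid over the plan's bounds with endpoints included and
#' poses as columns in lexicographic order (first parameter varying
#' fastest). Dimensions with a single point are frozen at the midpoint.
#'
#' @param plan a [sampling_plan()] in grid mode.
#' @param max_points guard against accidental combinatorial blow-up.
#' @return n_p x n_s parameter matrix with parameter names as row names.
#' @export
sample_training_grid <- function(plan, max_points = 1e5) {
  stopifnot(inherits(plan, "sampling_plan"), plan$mode == "grid")
  total <- prod(plan$points)
  if (total > max_points)
    stop("training grid would have ", total, " poses (> max_points)")
  axes <- lapply(seq_len(ncol(plan$bounds)), function(k) {
    lo <- plan$bounds[1, k]; hi <- plan$bounds[2, k]
    if (plan$points[k] == 1L) (lo + hi) / 2
    else seq(lo, hi, length.out = plan$points[k])
  })
  P <- t(as.matrix(do.call(expand.grid, axes)))
  rownames(P) <- colnames(plan$bounds)
  P
}

#' Seeded pseudorandom test set
#'
#' Uniform independent draws within the bounds, reproducible from the
#' plan's seed. Draws coinciding with a column of `avoid` (e.g. the
#' training grid) are resampled.
#'
#' @param plan a [sampling_plan()] in pseudorandom mode.
#' @param avoid optional n_p x m matrix of poses to avoid.
#' @return n_p x n parameter matrix with parameter names as row names.
#' @export
sample_test_set <- function(plan, avoid = NULL) {
  stopifnot(inherits(plan, "sampling_plan"), plan$mode == "pseudorandom")
  n_p <- ncol(plan$bounds)
  lo <- plan$bounds[1, ]; hi <- plan$bounds[2, ]
  P <- withr::with_seed(plan$seed, {
    draws <- matrix(stats::runif(n_p * plan$n, lo, hi), nrow = n_p)
    if (!is.null(avoid)) {
      for (j in seq_len(ncol(draws))) {
        while (any(colSums(abs(avoid - draws[, j])) < 1e-12))
          draws[, j] <- stats::runif(n_p, lo, hi)
      }
    }
    draws
  })
  rownames(P) <- colnames(plan$bounds)
  P
}

#' Save a surrogate model container
#'
#' Serialises the model into a single versioned binary container together
#' with a checksum of the payload; [load_model()] verifies both and
#' re-validates the model invariants.
#'
#' @param model a [offline_build()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  payload <- serialize(model, NULL, version = 3L)
  container <- list(format = "osteorom-surrogate", version = 1L,
                    checksum = payload_checksum(payload), payload = payload)
  saveRDS(container, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  container <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read surrogate container (corrupt or truncated file): ",
         conditionMessage(e)))
  if (!is.list(container) || !identical(container$format, "osteorom-surrogate"))
    stop("not an osteorom surrogate container")
  if (!identical(container$version, 1L))
    stop("unsupported container version: ", container$version)
  if (!identical(payload_checksum(container$payload), container$checksum))
    stop("checksum mismatch: surrogate container is corrupt")
  model <- unserialize(container$payload)
  # re-validate core invariants
  V <- model$basis$V
  if (nrow(V) != length(model$bone_nodes))
    stop("container invalid: basis row dimension mismatch")
  if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
    stop("container invalid: POD modes not orthonormal")
  if (model$interp$n_out != model$basis$n)
    stop("container invalid: interpolant output dimension mismatch")
  model
}

# Order-independent 64-bit-ish checksum of a raw vector (two parallel
# polynomial rolling sums over doubles; detects truncation and byte edits).
payload_checksum <- function(raw) {
  x <- as.integer(raw)
  n <- length(x)
  w1 <- ((seq_len(n) * 2654435761) %% 1000000007) / 1000000007
  s1 <- sum(x * w1) %% 999999937
  s2 <- sum(x * rev(w1)) %% 999999937
  sprintf("%.0f-%.0f-%d", s1 * 1e6, s2 * 1e6, n)
}
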