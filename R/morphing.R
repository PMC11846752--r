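#' Implant pose
#'
#' Rigid-body pose of the implant relative to its reference placement:
#' translations in mm and rotation angles in degrees. In 2D the parameters
#' are `(dx, dy, gamma)` (in-plane translation plus rotation about the
#' out-of-plane axis); in 3D `(dx, dy, dz, alpha, beta, gamma)` with
#' rotations about the x, y and z axes.
#'
#' @param ... either a single numeric vector of length 3 (2D) or 6 (3D), or
#'   named components `dx, dy, gamma` / `dx, dy, dz, alpha, beta, gamma`.
#' @return a named numeric vector of class `implant_pose`.
#' @export
#' @examples
#' implant_pose(dx = 0.5, dy = -0.2, gamma = 1)
implant_pose <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && length(args[[1]]) > 1L)
    args <- as.list(args[[1]])
  v <- unlist(args)
  nm2 <- c("dx", "dy", "gamma"); nm3 <- c("dx", "dy", "dz", "alpha", "beta", "gamma")
  if (is.null(names(v)) || all(names(v) == "")) {
    names(v) <- if (length(v) == 3L) nm2 else if (length(v) == 6L) nm3
                else if (length(v) == 1L) "dx"
                else stop("pose must have 1, 3 or 6 entries")
  } else {
    full <- if (all(names(v) %in% nm2) && !"dz" %in% names(v)) nm2 else nm3
    out <- stats::setNames(rep(0, length(full)), full)
    out[names(v)] <- v
    v <- out
  }
  if (!all(is.finite(v))) stop("pose entries must be finite")
  structure(v, class = "implant_pose")
}

pose_dim <- function(pose) {
  if (length(pose) >= 6L) 3L else if (length(pose) == 3L) 2L else 1L
}

#' Homogeneous rigid-body transformation matrix for a pose
#'
#' Builds the (d+1) x (d+1) homogeneous transform `T = R_x R_y R_z D`:
#' translation first, then rotations about the x, y and z axes in that
#' order (in 2D only the z-rotation block acts on the plane). Angles are
#' taken in degrees. By convention the rotation acts about `centre` (the
#' transform is conjugated with the translation to `centre`), so that with
#' `centre` at the implant centroid small rotations produce small node
#' displacements; the default `centre = 0` reproduces the plain
#' origin-centred composition.
#'
#' @param pose an [implant_pose()] (or coercible vector).
#' @param centre rotation centre, length-d numeric (default: origin).
#' @return (d+1) x (d+1) numeric matrix; the rotation block is orthogonal
#'   with determinant +1.
#' @export
transformation_matrix <- function(pose, centre = NULL) {
  pose <- if (inherits(pose, "implant_pose")) pose else implant_pose(pose)
  d <- pose_dim(pose)
  if (is.null(centre)) centre <- rep(0, d)
  rad <- pi / 180
  if (d == 1L) {
    T4 <- diag(2); T4[1, 2] <- pose[["dx"]]
  } else if (d == 2L) {
    g <- pose[["gamma"]] * rad
    Rz <- rbind(c(cos(g), sin(g), 0), c(-sin(g), cos(g), 0), c(0, 0, 1))
    D <- diag(3); D[1:2, 3] <- c(pose[["dx"]], pose[["dy"]])
    T4 <- Rz %*% D
  } else {
    a <- pose[["alpha"]] * rad; b <- pose[["beta"]] * rad; g <- pose[["gamma"]] * rad
    Rx <- rbind(c(1, 0, 0, 0), c(0, cos(a), -sin(a), 0),
                c(0, sin(a), cos(a), 0), c(0, 0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b), 0), c(0, 1, 0, 0),
                c(-sin(b), 0, cos(b), 0), c(0, 0, 0, 1))
    Rz <- rbind(c(cos(g), sin(g), 0, 0), c(-sin(g), cos(g), 0, 0),
                c(0, 0, 1, 0), c(0, 0, 0, 1))
    D <- diag(4); D[1:3, 4] <- c(pose[["dx"]], pose[["dy"]], pose[["dz"]])
    T4 <- Rx %*% Ry %*% Rz %*% D
  }
  if (any(centre != 0)) {
    Tc <- diag(d + 1L); Tc[seq_len(d), d + 1L] <- centre
    Tci <- diag(d + 1L); Tci[seq_len(d), d + 1L] <- -centre
    T4 <- Tc %*% T4 %*% Tci
  }
  unname(T4)
}

#' Assemble the Laplace operator partitioned by node set
#'
#' Assembles the scalar P1 Laplace stiffness matrix of the full mesh and
#' partitions it into the blocks associated with the fixed boundary
#' (`1`), the implant set (`2`) and the interior (`3`). The same scalar
#' operator drives every coordinate direction of the morph.
#'
#' @param mesh a [simplex_mesh()].
#' @return list with the sparse blocks `K11` ... `K33`, the index vectors
#'   `idx1`, `idx2`, `idx3`, and the full matrix `K`.
#' @export
assemble_laplace_operator <- function(mesh) {
  idx1 <- mesh$node_sets$fixed_boundary
  idx2 <- mesh$node_sets$implant
  idx3 <- mesh$node_sets$interior
  if (!length(idx3)) stop("empty interior node set: nothing to morph")
  K <- laplace_matrix(mesh)
  list(K = K,
       K31 = K[idx3, idx1, drop = FALSE],
       K32 = K[idx3, idx2, drop = FALSE],
       K33 = Matrix::forceSymmetric(K[idx3, idx3, drop = FALSE]),
       idx1 = idx1, idx2 = idx2, idx3 = idx3)
}

#' Precompute the static-condensation morph operator
#'
#' Factorises the interior Laplace block `K33` once (sparse Cholesky) and
#' precomputes the fixed-boundary contribution `-K33^{-1} K31 p_O1` and the
#' implant coupling `-K33^{-1} K32 H^T` against the homogeneous reference
#' coordinates `H` of the implant set. Morphing for a new pose then only
#' requires evaluating the transformation matrix and two small
#' matrix-vector products per coordinate direction.
#'
#' @param mesh the reference [simplex_mesh()].
#' @return an object of class `morph_operator`.
#' @export
build_morph_operator <- function(mesh) {
  blocks <- assemble_laplace_operator(mesh)
  if (!length(blocks$idx2))
    stop("empty implant node set: no boundary data to morph")
  d <- mesh$dim
  p1 <- mesh$nodes[blocks$idx1, , drop = FALSE]
  p2 <- mesh$nodes[blocks$idx2, , drop = FALSE]
  fac <- tryCatch(Matrix::Cholesky(blocks$K33, LDL = FALSE),
                  error = function(e)
                    stop("K33 is singular (disconnected interior): ",
                         conditionMessage(e)))
  H <- cbind(p2, 1)                                  # n2 x (d+1)
  x3_fixed <- as.matrix(Matrix::solve(fac, -(blocks$K31 %*% p1)))
  M2 <- as.matrix(Matrix::solve(fac, -(blocks$K32 %*% H)))  # n3 x (d+1)
  structure(list(
    idx1 = blocks$idx1, idx2 = blocks$idx2, idx3 = blocks$idx3,
    p1 = p1, H = H, x3_fixed = x3_fixed, M2 = M2,
    centre = colMeans(p2), dim = d, n_nodes = nrow(mesh$nodes),
    K = blocks$K, factor = fac
  ), class = "morph_operator")
}

#' Morph the node coordinates for an implant pose
#'
#' Applies the rigid transform of the pose to the implant node set and the
#' precomputed harmonic extension to the interior; fixed-boundary nodes are
#' returned bit-identically. Rotations act about the implant-set centroid
#' stored in the operator.
#'
#' @param op a [build_morph_operator()] result.
#' @param pose an [implant_pose()].
#' @return N x d matrix of morphed coordinates.
#' @export
morph <- function(op, pose) {
  pose <- if (inherits(pose, "implant_pose")) pose else implant_pose(pose)
  d <- op$dim
  if (pose_dim(pose) != d) stop("pose dimension does not match the operator")
  T4 <- transformation_matrix(pose, centre = op$centre)
  Tp <- t(T4[seq_len(d), , drop = FALSE])            # (d+1) x d
  x <- matrix(0, op$n_nodes, d, dimnames = list(NULL, colnames(op$p1)))
  x[op$idx1, ] <- op$p1
  x[op$idx2, ] <- op$H %*% Tp
  x[op$idx3, ] <- op$x3_fixed + op$M2 %*% Tp
  x
}

#' Morph the reference mesh and check its quality
#'
#' Returns a mesh with identical connectivity and node numbering whose
#' coordinates are morphed for `pose`. Inverted elements (which can occur
#' near the implant interface at large poses) are repaired by node
#' reordering; if elements remain below the quality tolerance afterwards a
#' morph-failure error naming them is raised. The indices flagged by the
#' initial quality check are attached as attribute `quality_report`.
#'
#' @param mesh reference [simplex_mesh()].
#' @param pose an [implant_pose()].
#' @param tol quality tolerance as a fraction of reference element volume.
#' @param op optional precomputed [build_morph_operator()] for `mesh`.
#' @return the morphed [simplex_mesh()].
#' @export
morph_mesh <- function(mesh, pose, tol = 0.01, op = NULL) {
  if (is.null(op)) op <- build_morph_operator(mesh)
  x <- morph(op, pose)
  out <- mesh
  out$nodes[] <- x
  failing <- check_mesh_quality(out, tol = tol)
  if (length(failing)) {
    vol <- element_volumes(out)
    inverted <- failing[vol[failing] < 0]
    out <- repair_inverted_elements(out, inverted)
    still <- check_mesh_quality(out, tol = tol)
    if (length(still))
      stop("morph failure: elements below quality tolerance after repair: ",
           paste(utils::head(still, 10L), collapse = ", "))
    # a fold-over inflates the unsigned volume sum above the domain volume
    if (sum(abs(element_volumes(out))) >
        (1 + 1e-8) * sum(abs(mesh$ref_volumes)))
      stop("morph failure: mesh folds over itself at this pose (",
           length(inverted), " inverted elements)")
  }
  attr(out, "quality_report") <- failing
  out
}

#' Discrete-harmonicity residual of morphed coordinates
#'
#' Maximum absolute residual of the interior rows of the Laplace system at
#' the given coordinates; near zero for any correctly morphed
#' configuration.
#'
#' @param op a [build_morph_operator()] result.
#' @param x N x d coordinate matrix (e.g. from [morph()]).
#' @return scalar residual.
#' @export
morph_residual <- function(op, x) {
  r <- op$K %*% x
  max(abs(r[op$idx3, ]))
}
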