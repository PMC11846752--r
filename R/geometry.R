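#' Simplex mesh with labelled node sets
#'
#' Container for a simplicial finite-element mesh (2-node segments, linear
#' triangles or linear tetrahedra) with the three disjoint node sets used by
#' the morphing pipeline: the fixed outer boundary (`fixed_boundary`), the
#' rigidly moving implant including its interface ring (`implant`), and the
#' remaining `interior` nodes whose coordinates are computed harmonically.
#'
#' Element volumes at construction time are stored as the reference volumes
#' against which later mesh-quality checks compare (see
#' [check_mesh_quality()]).
#'
#' @param nodes numeric N x d matrix of nodal coordinates (mm).
#' @param elements integer M x (d+1) matrix of 1-based node indices.
#' @param node_sets named list with integer index vectors `fixed_boundary`,
#'   `implant` and `interior`; together they must partition `1:N`.
#' @param element_material character vector of length M with entries
#'   `"bone"` or `"implant"`.
#' @param ref_volumes optional reference element volumes; defaults to the
#'   signed volumes of `elements` in `nodes`.
#' @param validate check all invariants (positive volumes, partition).
#' @return an object of class `simplex_mesh`.
#' @export
simplex_mesh <- function(nodes, elements, node_sets,
                         element_material = rep("bone", nrow(elements)),
                         ref_volumes = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  d <- ncol(nodes)
  if (ncol(elements) != d + 1L)
    stop("elements must have d+1 = ", d + 1L, " columns for a ", d, "D mesh")
  mesh <- structure(list(
    nodes = nodes, elements = elements, node_sets = node_sets,
    element_material = element_material, dim = d, ref_volumes = NULL
  ), class = "simplex_mesh")
  vol <- element_volumes(mesh)
  mesh$ref_volumes <- if (is.null(ref_volumes)) vol else ref_volumes
  if (validate) {
    n <- nrow(nodes)
    if (min(elements) < 1L || max(elements) > n)
      stop("element node indices out of range")
    all_idx <- sort(unlist(node_sets, use.names = FALSE))
    if (length(all_idx) != n || any(all_idx != seq_len(n)))
      stop("node_sets must partition the node indices 1..N")
    if (any(vol <= 0))
      stop("non-positive element volume in reference configuration (elements ",
           paste(utils::head(which(vol <= 0), 5L), collapse = ", "), ")")
    if (length(element_material) != nrow(elements))
      stop("element_material must have one entry per element")
    impl_nodes <- unique(as.vector(elements[element_material == "implant", ,
                                            drop = FALSE]))
    if (length(impl_nodes) && !all(impl_nodes %in% node_sets$implant))
      stop("implant node set must contain every node of implant elements")
  }
  mesh
}

#' @export
print.simplex_mesh <- function(x, ...) {
  cat(sprintf("simplex_mesh: %dD, %d nodes, %d elements (%d implant)\n",
              x$dim, nrow(x$nodes), nrow(x$elements),
              sum(x$element_material == "implant")))
  cat(sprintf("  node sets: fixed_boundary %d | implant %d | interior %d\n",
              length(x$node_sets$fixed_boundary), length(x$node_sets$implant),
              length(x$node_sets$interior)))
  invisible(x)
}

#' Specification of the synthetic reference domain
#'
#' Describes a rectangular (2D) or box-shaped (3D) bone domain with an
#' embedded axis-aligned convex implant inclusion at a reference placement,
#' the target element size of the structured simplex mesh, and the pose
#' bounds within which the implant may be rigidly repositioned. The implant
#' must sit strictly inside the outer domain with a clearance of at least
#' the largest admissible pose translation.
#'
#' @param outer numeric vector of outer extents (mm), length 2 or 3; the
#'   domain is `[0, outer[1]] x [0, outer[2]] (x [0, outer[3]])`.
#' @param implant `NULL` for a plain domain without inclusion, or a list
#'   with `centre` and `size` (full edge lengths, mm) of the axis-aligned
#'   implant box.
#' @param h target element size (mm); the structured grid spacing.
#' @param pose_bounds 2 x n_p matrix (rows `lower`, `upper`) of admissible
#'   pose parameters; defaults to translations in \[-1, 1\] mm and rotations
#'   in \[-1, 1\] degrees, matching the sampling ranges used throughout.
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(outer = c(10, 10),
                        implant = list(centre = c(5, 5), size = c(2, 4)),
                        h = 1 / 3,
                        pose_bounds = NULL) {
  d <- length(outer)
  if (!d %in% c(2L, 3L)) stop("outer extents must have length 2 or 3")
  if (is.null(pose_bounds)) pose_bounds <- default_pose_bounds(d)
  spec <- structure(list(outer = outer, implant = implant, h = h,
                         pose_bounds = pose_bounds, dim = d),
                    class = "domain_spec")
  if (!is.null(implant)) {
    lo <- implant$centre - implant$size / 2
    hi <- implant$centre + implant$size / 2
    clearance <- min(c(lo, outer - hi))
    max_shift <- max(abs(pose_bounds[, grepl("^d", colnames(pose_bounds)),
                                     drop = FALSE]))
    if (clearance <= 0)
      stop("geometry error: implant intersects or touches the outer boundary")
    if (clearance < max_shift)
      stop("geometry error: implant clearance ", signif(clearance, 3),
           " mm is smaller than the maximum pose translation ",
           signif(max_shift, 3), " mm")
  }
  spec
}

#' Default pose-parameter bounds
#'
#' Translations of the implant in \[-1, 1\] mm and rotations in \[-1, 1\]
#' degrees. In 2D the parameters are `(dx, dy, gamma)`, in 3D
#' `(dx, dy, dz, alpha, beta, gamma)`.
#'
#' @param d spatial dimension (2 or 3).
#' @return 2 x n_p matrix with rows `lower` and `upper`.
#' @export
default_pose_bounds <- function(d = 2L) {
  nm <- if (d == 2L) c("dx", "dy", "gamma")
        else c("dx", "dy", "dz", "alpha", "beta", "gamma")
  b <- rbind(lower = rep(-1, length(nm)), upper = rep(1, length(nm)))
  colnames(b) <- nm
  b
}

#' Build the synthetic reference mesh
#'
#' Generates a structured simplex mesh of the outer domain (triangles in 2D,
#' six tetrahedra per grid cell in 3D), labels elements whose centroid lies
#' inside the implant box as `"implant"`, and derives the three node sets:
#' the outer-boundary nodes (fixed during morphing), the implant nodes plus
#' a one-element-deep interface ring (rigidly moved), and the interior.
#'
#' @param spec a [domain_spec()].
#' @return a [simplex_mesh()].
#' @export
build_reference_domain <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  d <- spec$dim
  nn <- pmax(2L, as.integer(round(spec$outer / spec$h)) + 1L)
  axes <- lapply(seq_len(d), function(k) seq(0, spec$outer[k], length.out = nn[k]))
  nodes <- as.matrix(do.call(expand.grid, axes))
  colnames(nodes) <- c("x", "y", "z")[seq_len(d)]
  elements <- if (d == 2L) grid_triangles(nn) else grid_tetrahedra(nn, nodes)

  # implant classification by element centroid
  material <- rep("bone", nrow(elements))
  if (!is.null(spec$implant)) {
    lo <- spec$implant$centre - spec$implant$size / 2
    hi <- spec$implant$centre + spec$implant$size / 2
    if (any(spec$implant$size < 2 * spec$h))
      stop("refinement error: element size ", signif(spec$h, 3),
           " mm too coarse to resolve the implant")
    cent <- element_centroids(nodes, elements)
    inside <- rep(TRUE, nrow(elements))
    for (k in seq_len(d))
      inside <- inside & cent[, k] > lo[k] & cent[, k] < hi[k]
    material[inside] <- "implant"
    if (!any(inside))
      stop("refinement error: no element centroid falls inside the implant")
  }

  tol <- 1e-9 * max(spec$outer)
  on_bd <- rep(FALSE, nrow(nodes))
  for (k in seq_len(d))
    on_bd <- on_bd | nodes[, k] < tol | nodes[, k] > spec$outer[k] - tol
  omega1 <- which(on_bd)

  impl_elems <- which(material == "implant")
  impl_core <- unique(as.vector(elements[impl_elems, , drop = FALSE]))
  if (length(impl_core)) {
    # one-element-deep interface ring: nodes of every element touching the core
    touching <- which(matrixStats_any_in(elements, impl_core))
    omega2 <- sort(unique(as.vector(elements[touching, , drop = FALSE])))
    if (any(omega2 %in% omega1))
      stop("geometry error: implant interface ring reaches the outer boundary")
  } else {
    omega2 <- integer(0)
  }
  interior <- setdiff(seq_len(nrow(nodes)), union(omega1, omega2))
  simplex_mesh(nodes, elements,
               node_sets = list(fixed_boundary = omega1, implant = omega2,
                                interior = interior),
               element_material = material)
}

# rows of `elements` containing at least one index from `idx`
matrixStats_any_in <- function(elements, idx) {
  hit <- matrix(elements %in% idx, nrow = nrow(elements))
  rowSums(hit) > 0L
}

element_centroids <- function(nodes, elements) {
  d <- ncol(nodes)
  cent <- matrix(0, nrow(elements), d)
  for (a in seq_len(ncol(elements)))
    cent <- cent + nodes[elements[, a], , drop = FALSE]
  cent / ncol(elements)
}

grid_triangles <- function(nn) {
  nx <- nn[1]; ny <- nn[2]
  ij <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L))
  a <- (ij$j - 1L) * nx + ij$i        # (i, j)
  b <- a + 1L                         # (i+1, j)
  cc <- b + nx                        # (i+1, j+1)
  dd <- a + nx                        # (i, j+1)
  el <- rbind(cbind(a, b, cc), cbind(a, cc, dd))  # both counter-clockwise
  colnames(el) <- NULL
  el
}

grid_tetrahedra <- function(nn, nodes) {
  nx <- nn[1]; ny <- nn[2]; nz <- nn[3]
  ijk <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L),
                     k = seq_len(nz - 1L))
  base <- (ijk$k - 1L) * nx * ny + (ijk$j - 1L) * nx + ijk$i
  off <- function(di, dj, dk) base + di + dj * nx + dk * nx * ny
  v <- list(off(0,0,0), off(1,0,0), off(0,1,0), off(1,1,0),
            off(0,0,1), off(1,0,1), off(0,1,1), off(1,1,1))
  # Kuhn subdivision: six tets along the main diagonal v1 -> v8
  paths <- list(c(1,2,4,8), c(1,2,6,8), c(1,3,4,8),
                c(1,3,7,8), c(1,5,6,8), c(1,5,7,8))
  el <- do.call(rbind, lapply(paths, function(p)
    cbind(v[[p[1]]], v[[p[2]]], v[[p[3]]], v[[p[4]]])))
  # enforce positive orientation
  vol <- signed_simplex_volumes(nodes, el)
  neg <- vol < 0
  if (any(neg)) el[neg, c(3, 4)] <- el[neg, c(4, 3)]
  el
}

#' Signed element volumes
#'
#' Signed length/area/volume of every simplex via the determinant formula
#' `det([x_2 - x_1, ..., x_{d+1} - x_1]) / d!`. The sign encodes the node
#' ordering; a reflected ordering flips it.
#'
#' @param mesh a [simplex_mesh()].
#' @return numeric vector of length M (mm^d).
#' @export
element_volumes <- function(mesh) {
  signed_simplex_volumes(mesh$nodes, mesh$elements)
}

signed_simplex_volumes <- function(nodes, elements) {
  d <- ncol(nodes)
  if (any(apply(elements, 1L, anyDuplicated) > 0L))
    stop("degenerate element with repeated node index")
  if (d == 1L) {
    nodes[elements[, 2], 1] - nodes[elements[, 1], 1]
  } else if (d == 2L) {
    x1 <- nodes[elements[, 1], , drop = FALSE]
    x2 <- nodes[elements[, 2], , drop = FALSE]
    x3 <- nodes[elements[, 3], , drop = FALSE]
    ((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
       (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2])) / 2
  } else {
    x1 <- nodes[elements[, 1], , drop = FALSE]
    x2 <- nodes[elements[, 2], , drop = FALSE]
    x3 <- nodes[elements[, 3], , drop = FALSE]
    x4 <- nodes[elements[, 4], , drop = FALSE]
    a <- x2 - x1; b <- x3 - x1; c <- x4 - x1
    (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
       a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
       a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  }
}

#' Mesh-quality check against the reference configuration
#'
#' An element fails when its signed volume has dropped below `tol` times its
#' reference volume; in particular every inverted (negative-volume) element
#' fails for any `tol >= 0`.
#'
#' @param mesh a [simplex_mesh()] (possibly morphed; its `ref_volumes` are
#'   the volumes of the unmorphed reference configuration).
#' @param tol volume fraction threshold (default 0.01).
#' @return integer vector of failing element indices (empty when valid).
#' @export
check_mesh_quality <- function(mesh, tol = 0.01) {
  if (tol < 0) stop("tol must be >= 0")
  vol <- element_volumes(mesh)
  which(vol < tol * mesh$ref_volumes)
}

#' Repair inverted elements by node reordering
#'
#' Restores positive orientation of the listed inverted elements by swapping
#' their last two node indices (a single transposition flips the orientation
#' while preserving the element shape); node coordinates are untouched.
#' Listed elements that are not actually inverted are left unchanged with a
#' warning. Applying the repair twice is a no-op.
#'
#' @param mesh a [simplex_mesh()].
#' @param failing integer element indices (e.g. from [check_mesh_quality()]).
#' @return the repaired mesh.
#' @export
repair_inverted_elements <- function(mesh, failing) {
  if (!length(failing)) return(mesh)
  vol <- element_volumes(mesh)
  neg <- failing[vol[failing] < 0]
  skipped <- setdiff(failing, neg)
  if (length(skipped))
    warning("elements not inverted, left unchanged: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  if (length(neg)) {
    k <- ncol(mesh$elements)
    mesh$elements[neg, c(k - 1L, k)] <- mesh$elements[neg, c(k, k - 1L)]
  }
  mesh
}

#' Partition the bone elements into periprosthetic regions
#'
#' Splits the bone-labelled elements into `n_regions` disjoint zones as a
#' synthetic analogue of the Gruen zones used to report local bone change:
#' elements are assigned to the medial or lateral side of the implant centre
#' and each side is cut into equal-count bands along the implant's long
#' axis. With `n_regions = 1` a single region holds all bone elements.
#'
#' @param mesh a [simplex_mesh()].
#' @param n_regions number of regions (>= 1).
#' @param implant_centre optional implant reference centre; defaults to the
#'   centroid of the implant node set (or the domain centroid without one).
#' @return an object of class `region_map`: list with `regions` (named list
#'   of element-index vectors) and `n_regions`.
#' @export
define_regions <- function(mesh, n_regions, implant_centre = NULL) {
  stopifnot(n_regions >= 1)
  bone <- which(mesh$element_material == "bone")
  if (n_regions > length(bone))
    stop("n_regions exceeds the number of bone elements")
  if (is.null(implant_centre)) {
    idx <- mesh$node_sets$implant
    implant_centre <- if (length(idx)) colMeans(mesh$nodes[idx, , drop = FALSE])
                      else colMeans(mesh$nodes)
  }
  cent <- element_centroids(mesh$nodes, mesh$elements)[bone, , drop = FALSE]
  if (n_regions == 1L) {
    rm <- list(regions = list(region1 = bone), n_regions = 1L)
    class(rm) <- "region_map"
    return(validate_region_map(rm, mesh))
  }
  # bands run along y, the implant's long axis in the default spec
  axis <- 2L
  side <- ifelse(cent[, 1] <= implant_centre[1], "medial", "lateral")
  n_lat <- ceiling(n_regions / 2); n_med <- n_regions - n_lat
  assign_bands <- function(which_side, nb) {
    ids <- bone[side == which_side]
    if (!length(ids) || nb == 0L) return(list())
    y <- cent[side == which_side, axis]
    qs <- stats::quantile(y, probs = seq(0, 1, length.out = nb + 1L))
    band <- cut(y, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
    # unique() may merge degenerate quantiles; re-spread if needed
    split(ids, band)
  }
  parts <- c(assign_bands("lateral", n_lat), assign_bands("medial", n_med))
  if (length(parts) != n_regions)
    stop("could not form ", n_regions, " non-empty regions on this mesh")
  names(parts) <- paste0("region", seq_along(parts))
  rm <- list(regions = parts, n_regions = as.integer(n_regions))
  class(rm) <- "region_map"
  validate_region_map(rm, mesh)
}

validate_region_map <- function(rm, mesh) {
  bone <- which(mesh$element_material == "bone")
  all_ids <- sort(unlist(rm$regions, use.names = FALSE))
  if (anyDuplicated(all_ids) || !identical(all_ids, sort(bone)))
    stop("regions must partition the bone elements")
  rm
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map with", x$n_regions, "regions:",
      paste(vapply(x$regions, length, 1L), collapse = ", "), "elements\n")
  invisible(x)
}
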