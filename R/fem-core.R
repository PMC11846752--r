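# Shared P1 finite-element kernels: shape-function gradients, sparse
# operators (Laplace stiffness, consistent mass, linear elasticity) and
# boundary handling. All operators are assembled from triplets; the
# elasticity triplets are precomputed once per mesh and rescaled per
# remodelling step, since only the per-element density factor changes.

# Constant shape-function gradients and volumes for every element.
# Returns list(G = list over spatial directions of M x (d+1) matrices,
# V = positive element volumes).
p1_gradients <- function(mesh) {
  d <- mesh$dim
  el <- mesh$elements
  V <- signed_simplex_volumes(mesh$nodes, el)
  if (any(V <= 0))
    stop("p1_gradients requires positively oriented elements")
  if (d == 2L) {
    x <- matrix(mesh$nodes[el, 1], nrow(el)); y <- matrix(mesh$nodes[el, 2], nrow(el))
    b <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2])
    c_ <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1])
    G <- list(b / (2 * V), c_ / (2 * V))
  } else {
    m <- nrow(el)
    G <- replicate(d, matrix(0, m, d + 1L), simplify = FALSE)
    for (e in seq_len(m)) {
      X <- mesh$nodes[el[e, ], , drop = FALSE]
      C <- solve(cbind(1, X))           # row 1: constants, rows 2..d+1: gradients
      for (i in seq_len(d)) G[[i]][e, ] <- C[i + 1L, ]
    }
  }
  list(G = G, V = V)
}

# Scalar Laplace stiffness matrix (N x N, symmetric, rows sum to zero).
laplace_matrix <- function(mesh, geom = p1_gradients(mesh), subset = NULL) {
  el <- mesh$elements
  if (!is.null(subset)) el <- el[subset, , drop = FALSE]
  d <- mesh$dim; nv <- d + 1L
  sel <- if (is.null(subset)) seq_len(nrow(mesh$elements)) else subset
  ii <- jj <- xx <- vector("list", nv * nv)
  k <- 0L
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    k <- k + 1L
    v <- geom$V[sel] * Reduce(`+`, lapply(geom$G, function(Gd)
      Gd[sel, a] * Gd[sel, b]))
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]; xx[[k]] <- v
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2L))
}

# Consistent P1 mass matrix, optionally over an element subset.
mass_matrix <- function(mesh, geom = p1_gradients(mesh), subset = NULL) {
  d <- mesh$dim; nv <- d + 1L
  sel <- if (is.null(subset)) seq_len(nrow(mesh$elements)) else subset
  el <- mesh$elements[sel, , drop = FALSE]
  scale <- geom$V[sel] / ((d + 1) * (d + 2))
  ii <- jj <- xx <- vector("list", nv * nv)
  k <- 0L
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    k <- k + 1L
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]
    xx[[k]] <- scale * (1 + (a == b))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2L))
}

#' Boundary facets of a simplex mesh
#'
#' The (d-1)-dimensional faces (edges in 2D, triangles in 3D) that belong
#' to exactly one element; used to select traction surfaces.
#'
#' @param mesh a [simplex_mesh()].
#' @return matrix with d columns of node indices, one row per facet.
#' @export
boundary_facets <- function(mesh) {
  el <- mesh$elements
  d <- mesh$dim; nv <- d + 1L
  faces <- do.call(rbind, lapply(seq_len(nv), function(drop)
    el[, setdiff(seq_len(nv), drop), drop = FALSE]))
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

#' Select facets by a coordinate predicate
#'
#' Keeps the facets all of whose nodes satisfy `predicate`, e.g.
#' `function(xy) xy[, 2] > 10 - 1e-9` for the top edge of a 10 mm plate.
#'
#' @param mesh a [simplex_mesh()].
#' @param facets facet matrix (e.g. from [boundary_facets()]).
#' @param predicate function of an n x d coordinate matrix returning a
#'   logical vector (or scalar) per node.
#' @return the filtered facet matrix.
#' @export
facets_where <- function(mesh, facets, predicate) {
  keep <- apply(facets, 1L, function(f) all(predicate(mesh$nodes[f, , drop = FALSE])))
  facets[keep, , drop = FALSE]
}

facet_measures <- function(mesh, facets) {
  d <- mesh$dim
  if (d == 1L) return(rep(1, nrow(facets)))
  a <- mesh$nodes[facets[, 1], , drop = FALSE]
  b <- mesh$nodes[facets[, 2], , drop = FALSE]
  if (d == 2L) return(sqrt(rowSums((b - a)^2)))
  cc <- mesh$nodes[facets[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Dirichlet boundary condition
#'
#' @param nodes integer node indices.
#' @param comp displacement component(s) constrained: integer(s) in `1:d`
#'   or `"all"`.
#' @param value prescribed value (mm), recycled over nodes and components.
#' @return a `dirichlet_bc` list.
#' @export
dirichlet_bc <- function(nodes, comp = "all", value = 0) {
  structure(list(nodes = as.integer(nodes), comp = comp, value = value),
            class = "dirichlet_bc")
}

#' Surface-traction boundary condition
#'
#' Constant traction (N/mm^2) applied over a set of boundary facets;
#' converted to consistent nodal loads (equal vertex shares for P1).
#'
#' @param facets matrix of facet node indices (d columns).
#' @param traction numeric traction vector of length d.
#' @return a `traction_bc` list.
#' @export
traction_bc <- function(facets, traction) {
  structure(list(facets = as.matrix(facets), traction = traction),
            class = "traction_bc")
}

#' Load case for the mechanical problem
#'
#' @param dirichlet list of [dirichlet_bc()] entries; must remove all
#'   rigid-body modes.
#' @param neumann list of [traction_bc()] entries (may be empty).
#' @return a `load_case` list.
#' @export
load_case <- function(dirichlet, neumann = list()) {
  if (inherits(dirichlet, "dirichlet_bc")) dirichlet <- list(dirichlet)
  if (inherits(neumann, "traction_bc")) neumann <- list(neumann)
  if (!length(dirichlet))
    stop("at least one Dirichlet constraint is required")
  structure(list(dirichlet = dirichlet, neumann = neumann),
            class = "load_case")
}

# Expand a load case into fixed dof indices/values and the external force
# vector (length N*d). Dof numbering: node n, component k -> (n-1)*d + k.
expand_load_case <- function(mesh, loads) {
  d <- mesh$dim
  ndof <- nrow(mesh$nodes) * d
  fixed_idx <- integer(0); fixed_val <- numeric(0)
  for (bc in loads$dirichlet) {
    comps <- if (identical(bc$comp, "all")) seq_len(d) else as.integer(bc$comp)
    for (k in comps) {
      fixed_idx <- c(fixed_idx, (bc$nodes - 1L) * d + k)
      fixed_val <- c(fixed_val, rep_len(bc$value, length(bc$nodes)))
    }
  }
  dup <- duplicated(fixed_idx)
  fixed_idx <- fixed_idx[!dup]; fixed_val <- fixed_val[!dup]
  f <- numeric(ndof)
  for (bc in loads$neumann) {
    meas <- facet_measures(mesh, bc$facets)
    share <- meas / ncol(bc$facets)
    for (k in seq_len(d)) {
      idx <- (as.vector(bc$facets) - 1L) * d + k
      f_add <- rep(share, times = ncol(bc$facets)) * bc$traction[k]
      f <- f + accumulate_at(idx, f_add, ndof)
    }
  }
  if (!length(fixed_idx)) stop("no Dirichlet data: system is singular")
  list(fixed_idx = fixed_idx, fixed_val = fixed_val, f = f, ndof = ndof)
}

# Sum `vals` into a zero vector of length n at (possibly repeated) `idx`.
accumulate_at <- function(idx, vals, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc
  out
}

# Precompute elasticity stiffness triplets at unit density factor.
# K_e[(a,i),(b,j)] = V (lambda G_a^i G_b^j + mu G_a^j G_b^i
#                       + mu delta_ij sum_k G_a^k G_b^k),
# with lambda/mu per element (bone vs implant). Per-step assembly rescales
# each triplet by the density stiffness factor of its element.
elasticity_pattern <- function(mesh, params, geom = p1_gradients(mesh)) {
  d <- mesh$dim; nv <- d + 1L
  el <- mesh$elements
  m <- nrow(el)
  impl <- mesh$element_material == "implant"
  lam <- ifelse(impl, params$lambda_implant, params$lambda)
  mu <- ifelse(impl, params$mu_implant, params$mu)
  dot_ab <- function(a, b) Reduce(`+`, lapply(geom$G, function(Gd) Gd[, a] * Gd[, b]))
  nblk <- nv * nv * d * d
  ii <- jj <- xx <- ee <- vector("list", nblk)
  k <- 0L
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    gab <- dot_ab(a, b)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      k <- k + 1L
      v <- geom$V * (lam * geom$G[[i]][, a] * geom$G[[j]][, b] +
                     mu * geom$G[[j]][, a] * geom$G[[i]][, b] +
                     (i == j) * mu * gab)
      ii[[k]] <- (el[, a] - 1L) * d + i
      jj[[k]] <- (el[, b] - 1L) * d + j
      xx[[k]] <- v
      ee[[k]] <- seq_len(m)
    }
  }
  list(i = unlist(ii), j = unlist(jj), base = unlist(xx), elem = unlist(ee),
       ndof = nrow(mesh$nodes) * d, implant = impl)
}

assemble_elasticity <- function(pattern, stiffness_scale) {
  Matrix::sparseMatrix(i = pattern$i, j = pattern$j,
                       x = pattern$base * stiffness_scale[pattern$elem],
                       dims = c(pattern$ndof, pattern$ndof))
}

# Small-strain tensor components per element from nodal displacements.
# Columns: 2D (e11, e22, e12); 3D (e11, e22, e33, e12, e13, e23); 1D (e11).
element_strains <- function(mesh, u, geom = p1_gradients(mesh)) {
  d <- mesh$dim
  el <- mesh$elements
  grad <- function(i, j) { # d u_j / d x_i
    Reduce(`+`, lapply(seq_len(d + 1L), function(a)
      geom$G[[i]][, a] * u[el[, a], j]))
  }
  if (d == 1L) return(cbind(e11 = grad(1, 1)))
  if (d == 2L) {
    cbind(e11 = grad(1, 1), e22 = grad(2, 2),
          e12 = 0.5 * (grad(1, 2) + grad(2, 1)))
  } else {
    cbind(e11 = grad(1, 1), e22 = grad(2, 2), e33 = grad(3, 3),
          e12 = 0.5 * (grad(1, 2) + grad(2, 1)),
          e13 = 0.5 * (grad(1, 3) + grad(3, 1)),
          e23 = 0.5 * (grad(2, 3) + grad(3, 2)))
  }
}
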