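# Fixtures shared across the test files. Everything is generated in code;
# meshes are kept coarse so individual tests run in well under a second.

# Coarse 2D plate with an embedded implant (~200 elements).
small_spec <- function(h = 1) {
  domain_spec(outer = c(10, 10),
              implant = list(centre = c(5, 5), size = c(3, 4)),
              h = h)
}

small_domain <- function(h = 1) build_reference_domain(small_spec(h))

# Coarse 3D box with a box inclusion.
spec_3d <- function() {
  domain_spec(outer = c(6, 6, 6),
              implant = list(centre = c(3, 3, 3), size = c(2, 2, 2)),
              h = 1, pose_bounds = default_pose_bounds(3))
}

# Confined homogeneous bar under axial end traction. The interior
# remodelling equilibrium density solves Psi(rho*, eps(rho*)) = Psi_ref in
# closed form: rho* = rho0 * sqrt(sigma^2 / (2 (lambda + 2 mu) Psi_ref)),
# equivalently rho0 * sqrt(Psi_ref / Psi_LE(eps*)) at the equilibrium
# strain eps* = sigma / ((rho*/rho0)^2 (lambda + 2 mu)).
bar_fixture <- function(h = 0.5, L = 10, w = 2, sigma = 4) {
  spec <- domain_spec(outer = c(L, w), implant = NULL, h = h,
                      pose_bounds = default_pose_bounds(2))
  mesh <- build_reference_domain(spec)
  tol <- 1e-8
  left <- which(mesh$nodes[, 1] < tol)
  right_nodes <- which(mesh$nodes[, 1] > L - tol)
  fac <- boundary_facets(mesh)
  right <- facets_where(mesh, fac, function(xy) all(xy[, 1] > L - tol))
  loads <- load_case(
    dirichlet = list(dirichlet_bc(left, 1, 0),
                     dirichlet_bc(seq_len(nrow(mesh$nodes)), 2, 0)),
    neumann = traction_bc(right, c(sigma, 0)))
  params <- material_params()
  rho_star <- params$rho0 *
    sqrt(sigma^2 / (2 * (params$lambda + 2 * params$mu) * params$psi_ref))
  list(mesh = mesh, loads = loads, params = params, rho_star = rho_star,
       left = left, right_nodes = right_nodes, sigma = sigma, L = L)
}

# Displacement-controlled confined bar at prescribed end displacement.
bar_displacement_loads <- function(bar, d_end) {
  load_case(dirichlet = list(
    dirichlet_bc(bar$left, 1, 0),
    dirichlet_bc(seq_len(nrow(bar$mesh$nodes)), 2, 0),
    dirichlet_bc(bar$right_nodes, 1, d_end)))
}

# Three-node 1D chain: fixed node at 0, moving node at 1, one interior
# node at 0.5 whose harmonic position is the average of its neighbours.
chain_mesh <- function() {
  simplex_mesh(nodes = cbind(c(0, 0.5, 1)),
               elements = rbind(c(1L, 2L), c(2L, 3L)),
               node_sets = list(fixed_boundary = 1L, implant = 3L,
                                interior = 2L))
}

# Random strictly admissible 2D poses within the default bounds.
random_poses <- function(n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(3 * n, -1, 1), nrow = 3,
                                dimnames = list(c("dx", "dy", "gamma"), NULL)))
}

# One coarse surrogate shared by the surrogate/workflow tests (built once).
.fixture_cache <- new.env(parent = emptyenv())
tiny_surrogate <- function() {
  if (is.null(.fixture_cache$model)) {
    spec <- small_spec()
    plan <- sampling_plan("grid", spec$pose_bounds, points = c(3, 3, 1))
    .fixture_cache$model <- suppressWarnings(
      offline_build(spec, plan,
                    config = remodelling_config(max_steps = 150, tol = 2e-3)))
  }
  .fixture_cache$model
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}

# Synthetic snapshot set with a known response structure: region masses
# respond strictly monotonically to dx and are independent of gamma.
synthetic_snapshots <- function(n_s = 9) {
  mesh <- small_domain()
  bone <- which(mesh$element_material == "bone")
  bone_nodes <- sort(unique(as.vector(mesh$elements[bone, ])))
  P <- rbind(dx = seq(-1, 1, length.out = n_s),
             dy = rep(0, n_s),
             gamma = withr::with_seed(42, stats::runif(n_s, -1, 1)))
  S <- vapply(seq_len(n_s), function(i) {
    phi <- numeric(nrow(mesh$nodes))
    phi[bone_nodes] <- 1 + 0.3 * P["dx", i]
    phi[bone_nodes]
  }, numeric(length(bone_nodes)))
  rho_init <- matrix(1, nrow(mesh$elements), n_s)
  structure(list(S = S, P = P, bounds = default_pose_bounds(2),
                 rho_init = rho_init, bone_nodes = bone_nodes, mesh = mesh),
            class = "snapshot_set")
}

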