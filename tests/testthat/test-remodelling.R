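test_that("Lame parameters match the closed form and reject bad input", {
  lm <- lame_parameters(6500, 0.3)
  expect_equal(lm[["lambda"]], 3750)
  expect_equal(lm[["mu"]], 2500)
  lm0 <- lame_parameters(1000, 0)
  expect_equal(lm0[["lambda"]], 0)
  expect_equal(lm0[["mu"]], 500)
  expect_error(lame_parameters(-1, 0.3), "positive")
  expect_error(lame_parameters(1000, 0.5), "incompressible")
})

test_that("strain-energy density is quadratic in strain and density", {
  p <- material_params()
  expect_equal(strain_energy_density(c(0, 0, 0), 1, p), 0)
  # confined uniaxial strain 1e-3 at reference density
  eps <- c(1e-3, 0, 0)
  expect_equal(strain_energy_density(eps, 1, p), 0.004375)
  expect_equal(strain_energy_density(eps, 0.5, p), 0.25 * 0.004375)
})

test_that("stress is consistent with the energy quadratic form", {
  p <- material_params()
  expect_equal(as.numeric(stress(c(0, 0, 0), 1, p)), c(0, 0, 0))
  # at reference density the plain linear-elastic law is recovered
  eps <- c(2e-4, -1e-4, 5e-5)
  s1 <- stress(eps, p$rho0, p)
  tr <- eps[1] + eps[2]
  expect_equal(as.numeric(s1),
               c(p$lambda * tr + 2 * p$mu * eps[1],
                 p$lambda * tr + 2 * p$mu * eps[2],
                 2 * p$mu * eps[3]))
  # sigma : eps = 2 Psi for random strains and densities
  withr::with_seed(11, {
    for (k in 1:20) {
      eps <- stats::rnorm(3, sd = 1e-3)
      rho <- stats::runif(1, 0.2, 2)
      s <- as.numeric(stress(eps, rho, p))
      dot <- s[1] * eps[1] + s[2] * eps[2] + 2 * s[3] * eps[3]
      expect_equal(dot, 2 * strain_energy_density(eps, rho, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("mass source is signed by the energy imbalance", {
  p <- material_params()
  expect_equal(mass_source(p$psi_ref, p), 0)
  expect_equal(mass_source(0.004, p), 2e-5)
  p0 <- material_params(c = 1e-30)
  expect_equal(mass_source(10, p0), 1e-30 * (10 - 0.002))
})

test_that("gradient enhancement reduces to L2 projection and smooths", {
  mesh <- small_domain()
  p <- material_params()
  bone <- which(mesh$element_material == "bone")
  m <- nrow(mesh$elements)

  # constant density is reproduced exactly
  phi <- gradient_enhanced_projection(mesh, rep(1, m), p)
  bn <- attr(phi, "bone_nodes")
  expect_lt(max(abs(phi[bn] - 1)), 1e-10)

  # beta = 0 equals a dense L2-projection oracle
  withr::with_seed(5, rho <- stats::runif(m, 0.2, 2))
  p0 <- material_params(beta_ge = 0)
  phi0 <- gradient_enhanced_projection(mesh, rho, p0)
  M <- as.matrix(osteorom:::mass_matrix(mesh, subset = bone))[bn, bn]
  geom <- osteorom:::p1_gradients(mesh)
  d <- mesh$dim
  share <- geom$V[bone] * rho[bone] / (d + 1)
  b <- osteorom:::accumulate_at(as.vector(mesh$elements[bone, ]),
                                rep(share, d + 1), nrow(mesh$nodes))
  expect_lt(max(abs(phi0[bn] - solve(M, b[bn]))), 1e-10)

  # checkerboard density: enhancement strictly reduces nodal variance
  checker <- 1 + 0.5 * (-1)^seq_len(m)
  v_plain <- stats::var(gradient_enhanced_projection(mesh, checker, p0)[bn])
  v_enh <- stats::var(gradient_enhanced_projection(mesh, checker, p)[bn])
  expect_lt(v_enh, v_plain)

  p_bad <- material_params()
  p_bad$alpha_ge <- 0
  expect_error(gradient_enhanced_projection(mesh, rho, p_bad), "alpha_ge")
})

test_that("mechanical solve is exact for the homogeneous bar", {
  bar <- bar_fixture()
  p <- bar$params
  # zero load, zero prescribed displacement
  lc0 <- load_case(dirichlet = dirichlet_bc(seq_len(nrow(bar$mesh$nodes)),
                                            "all", 0))
  u0 <- mechanical_solve(bar$mesh, 1, lc0, p)
  expect_equal(max(abs(u0)), 0)
  # prescribed end displacement d over length L: uniform strain d/L
  lc1 <- bar_displacement_loads(bar, 0.01)
  u1 <- mechanical_solve(bar$mesh, 1, lc1, p)
  eps <- osteorom:::element_strains(bar$mesh, u1)
  expect_lt(max(abs(eps[, 1] - 0.001)), 1e-10)
  expect_lt(max(abs(eps[, 2:3])), 1e-10)
  expect_identical(attr(u1, "iterations"), 1L)
  # linearity: doubling the traction doubles the displacement
  u_t <- mechanical_solve(bar$mesh, 1, bar$loads, p)
  loads2 <- bar$loads
  loads2$neumann[[1]]$traction <- 2 * loads2$neumann[[1]]$traction
  u_2t <- mechanical_solve(bar$mesh, 1, loads2, p)
  expect_lt(max(abs(u_2t - 2 * u_t)), 1e-10)
  expect_error(
    mechanical_solve(bar$mesh, 1,
                     structure(list(dirichlet = list(), neumann = list()),
                               class = "load_case"), p),
    "Dirichlet")
})

test_that("density update clamps to physiological bounds", {
  p <- material_params()
  # Psi = Psi_ref is a fixed point
  eps_ref <- c(sqrt(p$psi_ref / (p$lambda / 2 + p$mu)), 0, 0)
  expect_equal(density_update(1, eps_ref, 1, 10, p), 1)
  # arithmetic: Psi = 0.004 -> rho_dot = 2e-5 -> 1.0002 after dt = 10
  eps4 <- c(sqrt(0.004 / (p$lambda / 2 + p$mu)), 0, 0)
  expect_equal(density_update(1, eps4, 1, 10, p), 1.0002)
  # an update beyond the upper bound saturates at rho_max = 2
  expect_equal(density_update(1.999, eps4, 1, 1e7, p), 2)
  expect_equal(density_update(0.002, c(0, 0, 0), 0.002, 1e7, p), p$rho_min)
})

test_that("the loaded bar relaxes to the closed-form equilibrium density", {
  bar <- bar_fixture()
  cfg <- remodelling_config(tol = 1e-6, max_steps = 500)
  state <- run_remodelling(bar$mesh, bar$loads, bar$params, cfg)
  expect_true(state$converged)
  rho <- state$rho[is.finite(state$rho)]
  expect_rel_equal(rho, bar$rho_star, 1e-4)
  # equilibrium strain is 1e-3 by construction of the traction
  expect_rel_equal(mean(state$eps[, 1]), 1e-3, 1e-3)
  # bound preservation along the whole trajectory
  expect_true(all(rho >= bar$params$rho_min & rho <= bar$params$rho_max))
  # monotone relaxation of the density error
  err <- abs(state$history$mean_rho - bar$rho_star)
  expect_true(all(diff(err) < 1e-12))
})

test_that("a state at equilibrium density is a fixed point", {
  bar <- bar_fixture()
  # displacement-controlled at the strain whose equilibrium is rho*
  lc <- bar_displacement_loads(bar, 0.01)
  cfg <- remodelling_config(tol = 1e-6, max_steps = 50)
  state <- run_remodelling(bar$mesh, lc, bar$params, cfg,
                           rho_init = bar$rho_star)
  expect_true(state$converged)
  expect_lte(state$steps, 1L)
  expect_rel_equal(state$rho[is.finite(state$rho)], bar$rho_star, 1e-6)
})

test_that("zero load drives the density to the physiological minimum", {
  bar <- bar_fixture()
  lc0 <- load_case(dirichlet = dirichlet_bc(seq_len(nrow(bar$mesh$nodes)),
                                            "all", 0))
  cfg <- remodelling_config(tol = 1e-9, max_steps = 300)
  state <- run_remodelling(bar$mesh, lc0, bar$params, cfg)
  rho <- state$rho[is.finite(state$rho)]
  expect_true(all(rho == bar$params$rho_min))
  # mean density decreased monotonically until the clamp
  expect_true(all(diff(state$history$mean_rho) <= 1e-15))
})

test_that("strain and density trajectories are translation-objective", {
  bar <- bar_fixture(h = 1)
  cfg <- remodelling_config(tol = 1e-4, max_steps = 60)
  lc_a <- bar_displacement_loads(bar, 0.008)
  # same relative stretch, whole Dirichlet data shifted by 0.5 mm
  n <- nrow(bar$mesh$nodes)
  lc_b <- load_case(dirichlet = list(
    dirichlet_bc(bar$left, 1, 0.5),
    dirichlet_bc(seq_len(n), 2, 0),
    dirichlet_bc(bar$right_nodes, 1, 0.508)))
  s_a <- suppressWarnings(run_remodelling(bar$mesh, lc_a, bar$params, cfg,
                                          rho_init = 0.9))
  s_b <- suppressWarnings(run_remodelling(bar$mesh, lc_b, bar$params, cfg,
                                          rho_init = 0.9))
  expect_lt(max(abs(s_a$eps - s_b$eps)), 1e-10)
  expect_lt(max(abs(s_a$rho - s_b$rho), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(s_b$u[, 1] - 0.5 - s_a$u[, 1])), 1e-10)
})

test_that("implant elements carry no density and never remodel", {
  mesh <- small_domain()
  spec <- small_spec()
  lc <- plate_load_case(mesh, spec)
  cfg <- remodelling_config(max_steps = 5, tol = 1e-9)
  state <- suppressWarnings(run_remodelling(mesh, lc, material_params(), cfg))
  impl <- mesh$element_material == "implant"
  expect_true(all(is.na(state$rho[impl])))
  expect_true(all(is.finite(state$rho[!impl])))
})

test_that("the tetrahedral path shares the full morph-and-remodel pipeline", {
  spec3 <- spec_3d()
  mesh3 <- build_reference_domain(spec3)
  op3 <- build_morph_operator(mesh3)
  pose <- implant_pose(c(0.3, -0.3, 0.3, 0.5, -0.5, 0.5))
  x <- morph(op3, pose)
  expect_lt(morph_residual(op3, x), 1e-8)
  i2 <- op3$idx2
  expect_lt(max(abs(dist(mesh3$nodes[i2, ]) - dist(x[i2, ]))), 1e-9)
  mm <- morph_mesh(mesh3, pose, op = op3)
  lc3 <- plate_load_case(mm, spec3)
  f3 <- initial_density_field(spec3)
  bone <- which(mm$element_material == "bone")
  cent <- osteorom:::element_centroids(mm$nodes, mm$elements)
  state <- suppressWarnings(run_remodelling(
    mm, lc3, material_params(), remodelling_config(max_steps = 20),
    rho_init = f3(cent[bone, ])))
  rho <- state$rho[is.finite(state$rho)]
  expect_true(all(rho >= 0.001 & rho <= 2))
  expect_length(state$phi, nrow(mm$nodes))
})
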