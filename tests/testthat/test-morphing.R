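test_that("transformation matrices compose rotations and translation", {
  expect_equal(transformation_matrix(implant_pose(c(0, 0, 0))), diag(3))
  T2 <- transformation_matrix(implant_pose(dx = 1))
  expect_equal(T2, matrix(c(1, 0, 0, 0, 1, 0, 1, 0, 1), 3))
  # rotation about x by 90 degrees maps (0, 1, 0) to (0, 0, 1)
  T3 <- transformation_matrix(implant_pose(c(0, 0, 0, 90, 0, 0)))
  expect_equal(as.numeric(T3 %*% c(0, 1, 0, 1)), c(0, 0, 1, 1),
               tolerance = 1e-12)
  # rotation blocks are orthogonal with determinant +1
  for (seed in 1:5) {
    pose <- withr::with_seed(seed, implant_pose(stats::runif(6, -30, 30)))
    R <- transformation_matrix(pose)[1:3, 1:3]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  expect_error(implant_pose(c(1, NA, 0)), "finite")
})

test_that("Laplace blocks are symmetric with zero row sums and SPD interior", {
  mesh <- small_domain()
  blocks <- assemble_laplace_operator(mesh)
  expect_lt(max(abs(blocks$K - Matrix::t(blocks$K))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(blocks$K))), 1e-10)
  expect_no_error(Matrix::Cholesky(blocks$K33, LDL = FALSE))
})

test_that("single interior node lands at the average of its neighbours", {
  chain <- chain_mesh()
  op <- build_morph_operator(chain)
  x <- morph(op, implant_pose(0.2))   # 1D: end node 1.0 -> 1.2
  expect_equal(x[1, 1], 0)
  expect_equal(x[3, 1], 1.2, tolerance = 1e-12)
  expect_equal(x[2, 1], 0.6, tolerance = 1e-12)
})

test_that("morph operator reproduces the identity and the dense oracle", {
  mesh <- small_domain(h = 1.25)      # 81 nodes <= 200
  expect_lte(nrow(mesh$nodes), 200L)
  op <- build_morph_operator(mesh)
  x0 <- morph(op, implant_pose(c(0, 0, 0)))
  expect_lt(max(abs(x0 - mesh$nodes)), 1e-10)
  expect_identical(dim(op$M2), c(length(op$idx3), mesh$dim + 1L))

  # dense full-system oracle: prescribe x1, x2 and solve the interior rows
  pose <- implant_pose(c(0.6, -0.4, 0.8))
  x <- morph(op, pose)
  K <- as.matrix(osteorom:::laplace_matrix(mesh))
  Tm <- transformation_matrix(pose, centre = op$centre)
  i1 <- op$idx1; i2 <- op$idx2; i3 <- op$idx3
  for (k in 1:2) {
    g2 <- cbind(mesh$nodes[i2, , drop = FALSE], 1) %*% Tm[k, ]
    rhs <- -K[i3, i1] %*% mesh$nodes[i1, k] - K[i3, i2] %*% g2
    x3 <- solve(K[i3, i3], rhs)
    expect_lt(max(abs(x[i3, k] - x3)), 1e-10)
  }
})

test_that("morphing is rigid on the implant and harmonic inside", {
  mesh <- small_domain()
  op <- build_morph_operator(mesh)
  i2 <- op$idx2
  d_ref <- dist(mesh$nodes[i2, ])
  for (j in seq_len(10)) {
    pose <- implant_pose(random_poses(10, seed = 99)[, j])
    x <- morph(op, pose)
    expect_identical(x[op$idx1, ], mesh$nodes[op$idx1, ])
    expect_lt(max(abs(dist(x[i2, ]) - d_ref)), 1e-10)
    expect_lt(morph_residual(op, x), 1e-8)
    # Omega_2 nodes equal the rigid transform of reference coordinates
    Tm <- transformation_matrix(pose, centre = op$centre)
    g <- cbind(mesh$nodes[i2, ], 1) %*% t(Tm[1:2, ])
    expect_lt(max(abs(x[i2, ] - g)), 1e-12)
  }
})

test_that("interior coordinates obey the discrete maximum principle", {
  mesh <- small_domain()
  op <- build_morph_operator(mesh)
  bd <- c(op$idx1, op$idx2)
  for (j in 1:5) {
    x <- morph(op, implant_pose(random_poses(5, seed = 3)[, j]))
    for (k in 1:2) {
      expect_gte(min(x[op$idx3, k]), min(x[bd, k]) - 1e-10)
      expect_lte(max(x[op$idx3, k]), max(x[bd, k]) + 1e-10)
    }
  }
})

test_that("morphing is linear in the boundary data for pure translations", {
  mesh <- small_domain()
  op <- build_morph_operator(mesh)
  p1 <- implant_pose(c(0.4, -0.3, 0)); p2 <- implant_pose(c(-0.2, 0.5, 0))
  x1 <- morph(op, p1); x2 <- morph(op, p2)
  x12 <- morph(op, implant_pose(c(0.2, 0.2, 0)))
  expect_lt(max(abs((x1 + x2 - mesh$nodes) - x12)), 1e-10)
})

test_that("morph_mesh keeps connectivity and fails loudly when crushed", {
  mesh <- small_domain()
  op <- build_morph_operator(mesh)
  m0 <- morph_mesh(mesh, implant_pose(c(0, 0, 0)), op = op)
  expect_equal(m0$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(m0$elements, mesh$elements)
  m1 <- morph_mesh(mesh, implant_pose(c(1, -1, 1)), op = op)
  expect_identical(dim(m1$nodes), dim(mesh$nodes))
  expect_identical(dim(m1$elements), dim(mesh$elements))
  expect_length(attr(m1, "quality_report"), 0L)
  # a translation of the order of the clearance crushes interface elements
  expect_error(morph_mesh(mesh, implant_pose(c(3.3, 0, 0)), op = op),
               "morph failure")
})

test_that("empty node sets are rejected by the operator assembly", {
  mesh <- small_domain()
  no_interior <- mesh
  no_interior$node_sets <- list(
    fixed_boundary = mesh$node_sets$fixed_boundary,
    implant = sort(c(mesh$node_sets$implant, mesh$node_sets$interior)),
    interior = integer(0))
  expect_error(assemble_laplace_operator(no_interior), "empty interior")
  spec <- domain_spec(outer = c(4, 4), implant = NULL, h = 1)
  plain <- build_reference_domain(spec)
  expect_error(build_morph_operator(plain), "empty implant")
})
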