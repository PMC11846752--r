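test_that("all six kernel families match hand-evaluated values", {
  expect_equal(kernel_eval(rbf_kernel("MQ", 0.7), 0), 1)
  expect_equal(kernel_eval(rbf_kernel("G", 2), 0.5), exp(-1))
  expect_equal(kernel_eval(rbf_kernel("MC4", 1), 1), 7 * exp(-1))
  expect_equal(kernel_eval(rbf_kernel("IMQ", 2), 0.5), 1 / sqrt(2))
  expect_equal(kernel_eval(rbf_kernel("MC0", 3), 1), exp(-3))
  expect_equal(kernel_eval(rbf_kernel("MC2", 2), 0.5), 2 * exp(-1))
  expect_equal(kernel_eval(rbf_kernel("MQ", 1), 1), sqrt(2))
  expect_error(kernel_eval(rbf_kernel("G", 1), -0.1), "nonnegative")
  expect_error(rbf_kernel("G", 0), "shape")
})

test_that("min-max normalisation is an exact affine bijection", {
  bounds <- rbind(lower = c(-1, 0, 10), upper = c(1, 5, 30))
  expect_equal(normalize_params(c(-1, 0, 10), bounds), c(0, 0, 0))
  expect_equal(normalize_params(c(1, 5, 30), bounds), c(1, 1, 1))
  expect_equal(normalize_params(c(0, 2.5, 20), bounds), c(0.5, 0.5, 0.5))
  withr::with_seed(2, P <- matrix(stats::runif(3 * 8, -1, 1), 3))
  P[2, ] <- P[2, ] * 2 + 2; P[3, ] <- P[3, ] * 10 + 20
  expect_lt(max(abs(denormalize_params(normalize_params(P, bounds), bounds) - P)),
            1e-14)
  bad <- rbind(lower = c(0, 1), upper = c(1, 1))
  expect_error(normalize_params(c(0.5, 1), bad), "degenerate")
})

test_that("interpolation is exact at the training centers", {
  bounds <- rbind(lower = c(-1, -1), upper = c(1, 1))
  withr::with_seed(4, {
    P <- matrix(stats::runif(2 * 7, -1, 1), 2)
    S_r <- matrix(stats::rnorm(3 * 7), 3)
  })
  for (fam in c("G", "IMQ", "MC0", "MC2", "MC4")) {
    for (aug in c(FALSE, TRUE)) {
      fit <- fit_rbf(S_r, P, rbf_kernel(fam, 1), bounds, augmented = aug)
      resid <- vapply(seq_len(7), function(i)
        max(abs(predict_weights(fit, P[, i]) - S_r[, i])), numeric(1))
      expect_lt(max(resid), 1e-8 * max(abs(S_r)))
    }
  }
  expect_error(fit_rbf(S_r[, c(1, 1:6)], P[, c(1, 1:6)],
                       rbf_kernel("G", 1), bounds), "duplicate")
  expect_warning(fit_rbf(S_r, P, rbf_kernel("MQ", 1), bounds,
                         augmented = FALSE), "conditionally")
})

test_that("plain kernel matrices are positive definite at moderate shape", {
  withr::with_seed(8, P <- matrix(stats::runif(2 * 9, 0, 1), 2))
  D <- as.matrix(dist(t(P)))
  for (fam in c("G", "IMQ", "MC0", "MC2", "MC4")) {
    B <- kernel_eval(rbf_kernel(fam, 1.5), D)
    expect_no_error(chol(B))
  }
})

test_that("augmented systems satisfy the side conditions and reproduce affine data", {
  bounds <- rbind(lower = c(0, 0), upper = c(2, 2))
  P <- rbind(c(0.1, 1.9, 0.2, 1.7, 1.0, 0.4), c(0.2, 0.3, 1.8, 1.6, 1.0, 0.9))
  f <- function(p) 2 * p[1] - 0.5 * p[2] + 1        # affine target
  S_r <- rbind(apply(P, 2, f))
  for (fam in c("G", "MQ", "IMQ", "MC0", "MC2", "MC4")) {
    fit <- fit_rbf(S_r, P, rbf_kernel(fam, 1), bounds, augmented = TRUE)
    # Eq-style orthogonality of coefficients to the polynomial tail
    Q <- cbind(1, t(fit$centers))
    expect_lt(max(abs(fit$A %*% Q)), 1e-8 * max(abs(fit$A)) + 1e-10)
    # exact affine reproduction at unseen points
    for (q in list(c(0.5, 0.5), c(1.3, 0.2), c(1.9, 1.9))) {
      expect_equal(predict_weights(fit, q), f(q), tolerance = 1e-8)
    }
  }
})

test_that("constant data yields a constant prediction everywhere", {
  bounds <- rbind(lower = c(-1, -1), upper = c(1, 1))
  withr::with_seed(6, P <- matrix(stats::runif(2 * 6, -1, 1), 2))
  fit <- fit_rbf(matrix(3.5, 1, 6), P, rbf_kernel("MC0", 0.5), bounds,
                 augmented = TRUE)
  for (q in list(c(0, 0), c(0.9, -0.9), c(-0.3, 0.7)))
    expect_equal(predict_weights(fit, q), 3.5, tolerance = 1e-10)
})

test_that("predictions are symmetric for symmetric training data", {
  bounds <- rbind(lower = c(-1, -1), upper = c(1, 1))
  P <- rbind(c(-1, 1, -1, 1, 0), c(-1, -1, 1, 1, 0))
  vals <- rbind(c(2, 2, 1, 1, 1.5))          # symmetric under x-reflection
  fit <- fit_rbf(vals, P, rbf_kernel("G", 1), bounds, augmented = FALSE)
  expect_equal(predict_weights(fit, c(0.4, 0.2)),
               predict_weights(fit, c(-0.4, 0.2)), tolerance = 1e-10)
})

test_that("predictions only see normalised distances (unit invariance)", {
  bounds1 <- rbind(lower = c(-1, -1), upper = c(1, 1))
  bounds2 <- rbind(lower = c(-1, -180), upper = c(1, 180))
  withr::with_seed(10, {
    P1 <- matrix(stats::runif(2 * 8, -1, 1), 2)
    S_r <- matrix(stats::rnorm(2 * 8), 2)
  })
  P2 <- P1; P2[2, ] <- P1[2, ] * 180          # rescale raw units of dim 2
  f1 <- fit_rbf(S_r, P1, rbf_kernel("IMQ", 1), bounds1)
  f2 <- fit_rbf(S_r, P2, rbf_kernel("IMQ", 1), bounds2)
  q <- c(0.25, 0.4)
  expect_equal(predict_weights(f1, q), predict_weights(f2, q * c(1, 180)),
               tolerance = 1e-10)
})

test_that("extrapolation beyond the training bounds warns", {
  bounds <- rbind(lower = c(-1, -1), upper = c(1, 1))
  withr::with_seed(3, P <- matrix(stats::runif(2 * 5, -1, 1), 2))
  fit <- fit_rbf(matrix(stats::rnorm(5), 1), P, rbf_kernel("G", 1), bounds)
  expect_warning(predict_weights(fit, c(1.5, 0)), "extrapolating")
})

test_that("shape sweep matches a brute-force argmin on a smooth function", {
  # 1-parameter smooth response, interpolated through a rank-1 'basis'
  bounds <- rbind(lower = 0, upper = 1)
  P_train <- rbind(seq(0, 1, length.out = 7))
  P_test <- rbind(c(0.07, 0.23, 0.55, 0.81, 0.94))
  f <- function(x) sin(2 * pi * x) + 0.3 * x
  basis <- structure(list(V = matrix(1, 1, 1), sv = 1, n = 1L),
                     class = "pod_basis")
  S_r_train <- rbind(f(P_train[1, ]))
  S_test <- rbind(f(P_test[1, ]))
  fams <- c("G", "MC2"); grid <- c(0.5, 1, 2, 4)
  tab <- shape_parameter_sweep(basis, S_r_train, P_train, S_test, P_test,
                               bounds, families = fams, a_grid = grid)
  expect_identical(nrow(tab), length(fams) * length(grid) * 2L)
  sel <- attr(tab, "selected")
  expect_lte(sel$mae, min(tab$mae, na.rm = TRUE))
  # independent brute force over the same cells
  brute <- expand.grid(family = fams, a = grid, augmented = c(FALSE, TRUE),
                       stringsAsFactors = FALSE)
  brute$mae <- vapply(seq_len(nrow(brute)), function(i) {
    fit <- fit_rbf(S_r_train, P_train, rbf_kernel(brute$family[i], brute$a[i]),
                   bounds, augmented = brute$augmented[i])
    mean(vapply(seq_len(ncol(P_test)), function(j)
      abs(predict_weights(fit, P_test[, j]) - S_test[1, j]), numeric(1)))
  }, numeric(1))
  best <- brute[order(brute$mae, brute$a), ][1, ]
  expect_identical(sel$family, best$family)
  expect_identical(sel$a, best$a)
  expect_identical(sel$augmented, best$augmented)
  expect_equal(sel$mae, best$mae, tolerance = 1e-12)
})
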