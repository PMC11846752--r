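#' Near-equilibrium heterogeneous initial BMD field
#'
#' Returns a smooth closed-form initial density: the interior remodelling
#' equilibrium of the confined column under the campaign traction,
#' modulated sinusoidally across the domain. Starting the campaign close
#' to a biomechanically equilibrated state mirrors how measured BMD
#' distributions are used to initialise patient-specific remodelling runs,
#' and keeps the adaptation signal dominated by the implant. Because the
#' field is a function of position it can be evaluated directly at morphed
#' element centroids, playing the role of projecting the initial BMD onto
#' each morphed mesh.
#'
#' The equilibrium base value solves `Psi = Psi_ref` for confined uniaxial
#' compression at traction magnitude `|t|`:
#' `rho_eq = rho0 sqrt(t^2 / (2 (lambda + 2 mu) Psi_ref))` (0.676 g/cm^3 at
#' the defaults).
#'
#' @param spec a [domain_spec()].
#' @param amplitude relative modulation amplitude (default 0.05).
#' @param params a [material_params()] used for the equilibrium base.
#' @param traction traction magnitude of the campaign load (N/mm^2).
#' @return function mapping an n x d coordinate matrix to densities.
#' @export
initial_density_field <- function(spec, amplitude = 0.05,
                                  params = material_params(), traction = 4) {
  outer <- spec$outer
  psi_confined <- traction^2 / (2 * (params$lambda + 2 * params$mu))
  base <- params$rho0 * sqrt(psi_confined / params$psi_ref)
  function(coords) {
    coords <- rbind(coords)
    mod <- Reduce(`*`, lapply(seq_len(ncol(coords)), function(k)
      sin(pi * coords[, k] / outer[k])))
    base * (1 + amplitude * mod)
  }
}

#' Confined-column load case: clamped bottom, guided sides, compressed top
#'
#' Clamps the bottom boundary, constrains the lateral boundaries to slide
#' vertically (roller conditions emulating the continuation of the
#' cortical shaft, which prevents the load from escaping sideways), and
#' applies a constant compressive traction on the top boundary standing in
#' for the joint load. All constrained facets lie on the fixed outer
#' boundary, so the identical load case applies unchanged to every morphed
#' mesh.
#'
#' @param mesh the reference [simplex_mesh()].
#' @param spec the [domain_spec()] the mesh was built from.
#' @param traction traction vector on the top boundary (N/mm^2); default
#'   4 N/mm^2 of compression along the last axis.
#' @return a [load_case()].
#' @export
plate_load_case <- function(mesh, spec, traction = NULL) {
  d <- mesh$dim
  if (is.null(traction)) { traction <- rep(0, d); traction[d] <- -4 }
  tol <- 1e-9 * max(spec$outer)
  bottom_nodes <- which(mesh$nodes[, d] < tol)
  lateral <- lapply(seq_len(d - 1L), function(k)
    dirichlet_bc(which(mesh$nodes[, k] < tol |
                         mesh$nodes[, k] > spec$outer[k] - tol), k, 0))
  facets <- boundary_facets(mesh)
  top <- facets_where(mesh, facets, function(xy) all(xy[, d] > spec$outer[d] - tol))
  if (!nrow(top)) stop("no facets found on the top boundary")
  load_case(dirichlet = c(list(dirichlet_bc(bottom_nodes, "all", 0)), lateral),
            neumann = traction_bc(top, traction))
}

#' Offline stage: snapshot campaign, POD and RBF fit
#'
#' Builds the reference mesh and morph operator, runs the high-fidelity
#' remodelling simulation at every training pose of the sampling plan
#' (morph, project the initial BMD, remodel to convergence, store the
#' final enhanced nodal field), computes the POD basis at the energy
#' tolerance `kappa` and fits the RBF interpolant to the reduced
#' coordinates. Poses whose morph or simulation fails are excluded and
#' logged in the result.
#'
#' @param spec a [domain_spec()].
#' @param plan a [sampling_plan()] in grid mode for the training poses.
#' @param params a [material_params()].
#' @param config a [remodelling_config()].
#' @param kappa POD energy tolerance (default 0.9999).
#' @param kernel an [rbf_kernel()] (default augmented Matern C0 with
#'   `a = 1e-4`).
#' @param augmented use the polynomial-augmented RBF system.
#' @param rho_init_fn initial-density function of position; default
#'   [initial_density_field()].
#' @param traction top-boundary traction passed to [plate_load_case()].
#' @param quality_tol mesh-quality tolerance for morphing.
#' @param verbose print per-pose progress.
#' @return an object of class `surrogate_model`.
#' @export
offline_build <- function(spec, plan = NULL, params = material_params(),
                          config = remodelling_config(), kappa = 0.9999,
                          kernel = rbf_kernel("MC0", 1e-4), augmented = TRUE,
                          rho_init_fn = NULL, traction = NULL,
                          quality_tol = 0.01, verbose = FALSE) {
  if (is.null(plan)) plan <- sampling_plan("grid", spec$pose_bounds, points = 3L)
  P <- sample_training_grid(plan)
  if (is.null(rho_init_fn)) rho_init_fn <- initial_density_field(spec)
  mesh <- build_reference_domain(spec)
  op <- build_morph_operator(mesh)
  loads <- plate_load_case(mesh, spec, traction = traction)
  bone <- which(mesh$element_material == "bone")
  bone_nodes <- sort(unique(as.vector(mesh$elements[bone, , drop = FALSE])))

  n_s <- ncol(P)
  snaps <- vector("list", n_s)
  inits <- vector("list", n_s)
  failed <- list()
  for (i in seq_len(n_s)) {
    pose <- implant_pose(P[, i])
    res <- tryCatch({
      run_high_fidelity(mesh, pose, loads, params, config,
                        rho_init_fn = rho_init_fn, op = op,
                        quality_tol = quality_tol)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- list(pose = P[, i],
                                            message = conditionMessage(res))
      if (verbose) message(sprintf("pose %d/%d FAILED: %s", i, n_s,
                                   conditionMessage(res)))
      next
    }
    snaps[[i]] <- res$state$phi[bone_nodes]
    inits[[i]] <- res$rho_init
    if (verbose) message(sprintf("pose %d/%d: %d steps, mean BMD %.4f",
                                 i, n_s, res$state$steps,
                                 mean(res$state$rho[bone])))
  }
  ok <- !vapply(snaps, is.null, logical(1))
  if (sum(ok) < 2L)
    stop("fewer than 2 successful snapshots; cannot build a surrogate")
  S <- do.call(cbind, snaps[ok])
  P_ok <- P[, ok, drop = FALSE]
  rho_init_mat <- do.call(cbind, inits[ok])

  # interpolate only over parameters that actually vary in the plan
  active <- as.integer(which(apply(P_ok, 1L, function(r) max(r) - min(r) > 0)))
  if (!length(active))
    stop("degenerate pose bounds: no active parameter dimension")
  frozen <- P_ok[setdiff(seq_len(nrow(P_ok)), active), 1]

  basis <- compute_pod(S, kappa = kappa)
  S_r <- pod_reduce(basis, S)
  interp <- fit_rbf(S_r, P_ok[active, , drop = FALSE], kernel,
                    bounds = plan$bounds[, active, drop = FALSE],
                    augmented = augmented)
  snapshots <- structure(list(S = S, P = P_ok, bounds = plan$bounds,
                              rho_init = rho_init_mat,
                              bone_nodes = bone_nodes, mesh = mesh),
                         class = "snapshot_set")
  structure(list(
    basis = basis, interp = interp, mesh = mesh, op = op, spec = spec,
    loads = loads, params = params, config = config,
    active = active, frozen = frozen,
    bone_nodes = bone_nodes, rho_init_fn = rho_init_fn,
    snapshots = snapshots, failed = failed,
    provenance = list(kappa = kappa, kernel = kernel$family, a = kernel$a,
                      augmented = augmented, plan = plan,
                      n_snapshots = sum(ok), n_failed = length(failed),
                      quality_tol = quality_tol,
                      built = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "surrogate_model: %d snapshots (%d failed), %d POD modes, %s(a = %g)%s\n",
    x$provenance$n_snapshots, x$provenance$n_failed, x$basis$n,
    x$provenance$kernel, x$provenance$a,
    if (x$provenance$augmented) " augmented" else ""))
  invisible(x)
}

#' One high-fidelity bone-remodelling run at a pose
#'
#' Morphs the reference mesh, evaluates the initial-density field at the
#' morphed element centroids, and runs the remodelling solver to
#' convergence. This is the expensive path that the surrogate replaces.
#'
#' @param mesh reference [simplex_mesh()].
#' @param pose an [implant_pose()].
#' @param loads a [load_case()] (on the fixed outer boundary).
#' @param params,config solver parameters.
#' @param rho_init_fn initial-density function of position.
#' @param op optional precomputed morph operator.
#' @param quality_tol mesh-quality tolerance.
#' @return list with the converged `state` ([run_remodelling()] result),
#'   the morphed `mesh` and the per-element `rho_init` used.
#' @export
run_high_fidelity <- function(mesh, pose, loads, params = material_params(),
                              config = remodelling_config(),
                              rho_init_fn = NULL, op = NULL,
                              quality_tol = 0.01) {
  morphed <- morph_mesh(mesh, pose, tol = quality_tol, op = op)
  bone <- which(morphed$element_material == "bone")
  cent <- element_centroids(morphed$nodes, morphed$elements)
  rho_init <- rep(NA_real_, nrow(morphed$elements))
  rho_init[bone] <- if (is.null(rho_init_fn)) params$rho0
                    else rho_init_fn(cent[bone, , drop = FALSE])
  state <- run_remodelling(morphed, loads, params, config,
                           rho_init = rho_init[bone])
  list(state = state, mesh = morphed, rho_init = rho_init)
}

#' Online stage: predict the BMD field for a new pose
#'
#' Evaluates the RBF weights at the pose and forms the linear combination
#' of POD modes; no finite-element solve is involved. The field is
#' returned on all reference-mesh nodes (implant-only nodes carry 0, as in
#' the snapshots). With `morph = TRUE` the morphed mesh for visualisation
#' is attached as attribute `mesh`.
#'
#' @param model a [offline_build()] result.
#' @param pose an [implant_pose()] (raw units).
#' @param morph also morph the mesh for visualisation.
#' @return numeric nodal BMD field of length N.
#' @export
online_predict <- function(model, pose, morph = FALSE) {
  pose <- if (inherits(pose, "implant_pose")) pose else implant_pose(pose)
  pv <- as.numeric(pose)
  inactive <- setdiff(seq_along(pv), model$active)
  if (length(inactive) && any(abs(pv[inactive] - model$frozen) > 1e-9))
    warning("pose deviates in parameters frozen during training; ",
            "those components are ignored")
  w <- predict_weights(model$interp, pv[model$active])
  phi_b <- pod_reconstruct(model$basis, w)
  phi <- numeric(nrow(model$mesh$nodes))
  phi[model$bone_nodes] <- phi_b
  if (morph)
    attr(phi, "mesh") <- morph_mesh(model$mesh, pose, op = model$op)
  phi
}

#' Mean absolute error between two nodal fields
#'
#' `e = (1/n) sum_i |phi_i - phi_tilde_i|` (g/cm^3).
#'
#' @param predicted,reference numeric vectors of equal length.
#' @return nonnegative scalar; zero iff the fields are identical.
#' @export
evaluate_mae <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("field lengths differ: ", length(predicted), " vs ",
         length(reference))
  mean(abs(predicted - reference))
}

#' Holdout validation of the surrogate against high-fidelity runs
#'
#' Runs the full high-fidelity pipeline at each test pose, compares it
#' with the online prediction, and reports the per-pose MAE (over the bone
#' nodes), their mean, and a per-region MAE table. Poses whose
#' high-fidelity run fails are skipped and logged.
#'
#' @param model a [offline_build()] result.
#' @param test_poses n_p x n_test matrix of poses (e.g. from
#'   [sample_test_set()]).
#' @param regions optional [define_regions()] result for the region table
#'   (default: 7 regions).
#' @return list with `mae` (per pose), `mean_mae`, `region_mae` (data
#'   frame), `dynamic_range` of the high-fidelity fields, `fields`
#'   (high-fidelity and predicted matrices over bone nodes) and `skipped`.
#' @export
validate_holdout <- function(model, test_poses, regions = NULL) {
  test_poses <- cbind(test_poses)
  if (is.null(regions)) regions <- define_regions(model$mesh, 7L)
  bn <- model$bone_nodes
  n_t <- ncol(test_poses)
  hf <- pred <- matrix(NA_real_, length(bn), n_t)
  skipped <- list()
  for (j in seq_len(n_t)) {
    pose <- implant_pose(test_poses[, j])
    res <- tryCatch(
      run_high_fidelity(model$mesh, pose, model$loads, model$params,
                        model$config, rho_init_fn = model$rho_init_fn,
                        op = model$op,
                        quality_tol = model$provenance$quality_tol),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- list(pose = test_poses[, j],
                                              message = conditionMessage(res))
      next
    }
    hf[, j] <- res$state$phi[bn]
    pred[, j] <- online_predict(model, pose)[bn]
  }
  ok <- which(!is.na(hf[1, ]))
  if (!length(ok)) stop("every high-fidelity holdout run failed")
  mae <- vapply(ok, function(j) evaluate_mae(pred[, j], hf[, j]), numeric(1))
  # region-wise MAE over the nodes of each region's elements
  reg_mae <- vapply(regions$regions, function(ids) {
    nodes_r <- intersect(unique(as.vector(model$mesh$elements[ids, ])), bn)
    ridx <- match(nodes_r, bn)
    mean(vapply(ok, function(j)
      evaluate_mae(pred[ridx, j], hf[ridx, j]), numeric(1)))
  }, numeric(1))
  list(mae = mae, mean_mae = mean(mae),
       region_mae = data.frame(region = names(regions$regions),
                               mae = unname(reg_mae)),
       dynamic_range = max(hf[, ok]) - min(hf[, ok]),
       fields = list(hf = hf[, ok, drop = FALSE],
                     predicted = pred[, ok, drop = FALSE],
                     poses = test_poses[, ok, drop = FALSE]),
       skipped = skipped)
}
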