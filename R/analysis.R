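#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of the average-rank variables:
#' `rho = cov(R(x), R(y)) / (sd(R(x)) sd(R(y)))`. Ties receive average
#' ranks. A constant input makes the coefficient undefined; `NA` is
#' returned with attribute `undefined = TRUE` and a warning, never a
#' silent zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar in \[-1, 1\], or flagged `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations are required")
  rx <- rank(x); ry <- rank(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0) {
    warning("constant input: Spearman coefficient undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  as.numeric(stats::cov(rx, ry) / (sx * sy))
}

#' Relative mass change per region
#'
#' For each region, `100 * (m_final - m_init) / m_init` with the mass
#' `m = sum_e rho_e V_e` over the region's elements. When a nodal field is
#' supplied, the element-centre density is the mean of its vertex values.
#'
#' @param mesh a [simplex_mesh()].
#' @param regions a [define_regions()] result.
#' @param rho_init,rho_final densities: per-element vectors (length M) or
#'   nodal fields (length N).
#' @return named numeric vector of percentage changes; regions with zero
#'   initial mass yield flagged `NA`.
#' @export
mass_change_by_region <- function(mesh, regions, rho_init, rho_final) {
  vol <- abs(element_volumes(mesh))
  to_elem <- function(x) {
    if (length(x) == nrow(mesh$elements)) return(x)
    if (length(x) == nrow(mesh$nodes))
      return(rowMeans(matrix(x[mesh$elements], nrow(mesh$elements))))
    stop("density must be per-element (M) or nodal (N)")
  }
  ri <- to_elem(rho_init); rf <- to_elem(rho_final)
  out <- vapply(regions$regions, function(ids) {
    m0 <- sum(ri[ids] * vol[ids]); m1 <- sum(rf[ids] * vol[ids])
    if (m0 == 0) return(NA_real_)
    100 * (m1 - m0) / m0
  }, numeric(1))
  if (anyNA(out)) {
    warning("region with zero initial mass: change undefined")
    attr(out, "undefined") <- which(is.na(out))
  }
  out
}

#' Sensitivity and mass-change diagnostics over a snapshot campaign
#'
#' For every pose parameter and region, the Spearman correlation between
#' the parameter values across snapshots and the region's percentage mass
#' change (plus an `all`-bone column), together with the median/min/max
#' mass-change summary per region.
#'
#' @param snapshots a `snapshot_set` (the `$snapshots` component of an
#'   [offline_build()] model).
#' @param regions a [define_regions()] result for the snapshot mesh.
#' @return list with `sensitivity` (n_p x (n_regions + 1) matrix of
#'   Spearman coefficients), `mass_change` (region x snapshot matrix, %),
#'   and `summary` (data frame of median/min/max per region).
#' @export
sensitivity_campaign <- function(snapshots, regions) {
  stopifnot(inherits(snapshots, "snapshot_set"))
  n_s <- ncol(snapshots$S)
  if (n_s < 3L) stop("at least 3 snapshots are required")
  mesh <- snapshots$mesh
  bone <- which(mesh$element_material == "bone")
  all_regions <- c(regions$regions, list(all = bone))
  rmap <- list(regions = all_regions)
  mc <- vapply(seq_len(n_s), function(i) {
    phi <- numeric(nrow(mesh$nodes))
    phi[snapshots$bone_nodes] <- snapshots$S[, i]
    ri <- snapshots$rho_init[, i]
    ri[!is.finite(ri)] <- 0
    mass_change_by_region(mesh, rmap, ri, phi)
  }, numeric(length(all_regions)))
  rownames(mc) <- names(all_regions)
  n_p <- nrow(snapshots$P)
  sens <- matrix(NA_real_, n_p, nrow(mc),
                 dimnames = list(rownames(snapshots$P), rownames(mc)))
  for (p in seq_len(n_p)) for (r in seq_len(nrow(mc)))
    sens[p, r] <- suppressWarnings(spearman_rho(snapshots$P[p, ], mc[r, ]))
  list(sensitivity = sens,
       mass_change = mc,
       summary = data.frame(region = rownames(mc),
                            median = apply(mc, 1, stats::median),
                            min = apply(mc, 1, min),
                            max = apply(mc, 1, max),
                            row.names = NULL))
}

#' Bar chart of region-wise sensitivities
#'
#' @param sens sensitivity matrix from [sensitivity_campaign()].
#' @param region column to plot (default `"all"`).
#' @param ... passed to [graphics::barplot()].
#' @export
plot_sensitivity <- function(sens, region = "all", ...) {
  graphics::barplot(sens[, region], ylim = c(-1, 1),
                    ylab = "Spearman rho", main = paste("region:", region), ...)
  graphics::abline(h = 0)
  invisible(sens)
}
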