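#' Define a clustering scenario
#'
#' A scenario is the generative parameter tuple of a simulated clustering
#' condition: the overall localization density, the percentage of points
#' that belong to clusters, the number of points per cluster, and the
#' maximum distance of a clustered point from its cluster seed (the
#' effective cluster radius).  A cluster model selects how points are
#' arranged around each seed.
#'
#' @param overall_density Points per square micrometre (> 0).
#' @param pct_clustered Percent of points in clusters, in `[0, 100]`.
#' @param points_per_cluster Integer >= 1.
#' @param cluster_radius_nm Maximum point-to-seed distance, nm (> 0).
#' @param cluster_model One of `"uniform-disc"`, `"gaussian"`, `"fiber"`,
#'   `"ring"`, `"sphere-3d"`.
#' @param axial_range_nm Axial (z) extent in nm for 3D simulation; `0`
#'   keeps the field two-dimensional.
#' @return An object of class `cluster_scenario`.
#' @examples
#' cluster_scenario(100, 50, 10, 30)
#' @export
cluster_scenario <- function(overall_density, pct_clustered,
                             points_per_cluster, cluster_radius_nm,
                             cluster_model = "uniform-disc",
                             axial_range_nm = 0) {
  if (!is.finite(overall_density) || overall_density <= 0)
    abort_param("overall_density must be positive, got %s", overall_density)
  if (!is.finite(pct_clustered) || pct_clustered < 0 || pct_clustered > 100)
    abort_param("pct_clustered must lie in [0, 100], got %s", pct_clustered)
  if (!is.finite(points_per_cluster) || points_per_cluster < 1)
    abort_param("points_per_cluster must be >= 1, got %s", points_per_cluster)
  if (!is.finite(cluster_radius_nm) || cluster_radius_nm <= 0)
    abort_param("cluster_radius_nm must be positive, got %s", cluster_radius_nm)
  models <- c("uniform-disc", "gaussian", "fiber", "ring", "sphere-3d")
  cluster_model <- match.arg(cluster_model, models)
  if (cluster_model == "sphere-3d" && axial_range_nm <= 0)
    abort_param("sphere-3d scenarios need axial_range_nm > 0")
  structure(list(
    overall_density = overall_density,
    pct_clustered = pct_clustered,
    points_per_cluster = as.integer(points_per_cluster),
    cluster_radius_nm = cluster_radius_nm,
    cluster_model = cluster_model,
    axial_range_nm = axial_range_nm
  ), class = "cluster_scenario")
}

#' @export
print.cluster_scenario <- function(x, ...) {
  cat(sprintf(
    "cluster_scenario: %g pts/um^2, %g%% clustered, %d pts/cluster, r = %g nm [%s%s]\n",
    x$overall_density, x$pct_clustered, x$points_per_cluster,
    x$cluster_radius_nm, x$cluster_model,
    if (x$axial_range_nm > 0) sprintf(", z range %g nm", x$axial_range_nm) else ""))
  invisible(x)
}

#' Enumerate scenarios over parameter ranges
#'
#' Forms the full Cartesian product of the supplied parameter values, in
#' deterministic lexicographic order (the last range varies fastest).
#'
#' @param ranges Named list with non-empty numeric vectors `density`,
#'   `pct`, `ppc`, `radius`.
#' @inheritParams cluster_scenario
#' @return List of `cluster_scenario` objects.
#' @examples
#' length(enumerate_scenarios(list(density = c(50, 100), pct = 50,
#'                                 ppc = 10, radius = c(30, 40))))
#' @export
enumerate_scenarios <- function(ranges, cluster_model = "uniform-disc",
                                axial_range_nm = 0) {
  needed <- c("density", "pct", "ppc", "radius")
  for (nm in needed) {
    if (is.null(ranges[[nm]]) || length(ranges[[nm]]) == 0)
      abort_param("range '%s' must be non-empty", nm)
  }
  grid <- expand.grid(radius = ranges$radius, ppc = ranges$ppc,
                      pct = ranges$pct, density = ranges$density,
                      KEEP.OUT.ATTRS = FALSE)
  # lexicographic in (density, pct, ppc, radius)
  grid <- grid[order(grid$density, grid$pct, grid$ppc, grid$radius), ]
  lapply(seq_len(nrow(grid)), function(i) {
    cluster_scenario(grid$density[i], grid$pct[i], grid$ppc[i],
                     grid$radius[i], cluster_model, axial_range_nm)
  })
}

#' Assess whether a scenario is viable for training
#'
#' Applies the viability filter used to assemble training conditions:
#' a scenario is kept when it yields between 1 and 5 clusters per square
#' micrometre (inclusive) and a point density inside clusters between
#' 1.5x and 100x the non-clustered density (inclusive).  The in-cluster
#' density is the per-cluster point count divided by the area of one
#' cluster (`pi r^2` for disc-like clusters); the outside density divides
#' the non-clustered points by the cell area minus the summed cluster
#' area.
#'
#' @param scenario A `cluster_scenario`.
#' @param cell A `cell_shape`; only its area enters the calculation.
#' @return A list of class `viability_result` with `clusters_per_um2`,
#'   `density_inside`, `density_outside`, `density_ratio` (all per um^2)
#'   and logical `viable`.
#' @examples
#' assess_viability(cluster_scenario(100, 50, 10, 30), generate_cell_shape(1))
#' @export
assess_viability <- function(scenario, cell = generate_cell_shape()) {
  stopifnot(inherits(scenario, "cluster_scenario"))
  area_um2 <- cell$area_um2
  p <- scenario$pct_clustered / 100
  clusters_per_um2 <- scenario$overall_density * p / scenario$points_per_cluster
  cluster_area_um2 <- pi * (scenario$cluster_radius_nm / 1000)^2
  total_cluster_area <- clusters_per_um2 * area_um2 * cluster_area_um2
  if (total_cluster_area >= area_um2)
    abort_param(
      "degenerate scenario: total cluster area (%.1f um^2) >= cell area (%.1f um^2)",
      total_cluster_area, area_um2)

  if (p > 0) {
    density_inside <- scenario$points_per_cluster / cluster_area_um2
    density_outside <- scenario$overall_density * (1 - p) * area_um2 /
      (area_um2 - total_cluster_area)
    density_ratio <- density_inside / density_outside
  } else {
    density_inside <- 0
    density_outside <- scenario$overall_density
    density_ratio <- NA_real_
  }
  viable <- clusters_per_um2 >= 1 && clusters_per_um2 <= 5 &&
    !is.na(density_ratio) && density_ratio >= 1.5 && density_ratio <= 100
  structure(list(
    clusters_per_um2 = clusters_per_um2,
    density_inside = density_inside,
    density_outside = density_outside,
    density_ratio = density_ratio,
    viable = viable
  ), class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf(
    "viability: %.3g clusters/um^2, inside %.4g /um^2, outside %.4g /um^2, ratio %.3g -> %s\n",
    x$clusters_per_um2, x$density_inside, x$density_outside,
    x$density_ratio, if (x$viable) "viable" else "not viable"))
  invisible(x)
}

#' Default training scenario grid
#'
#' The parameter ranges used to assemble training conditions: overall
#' densities 50-500 per um^2, 10-90 percent clustered, 5-100 points per
#' cluster (bounded by the widest model input window), and cluster radii
#' 10-100 nm.
#'
#' @inheritParams enumerate_scenarios
#' @return List of `cluster_scenario` objects (unfiltered).
#' @export
default_training_grid <- function(cluster_model = "uniform-disc",
                                  axial_range_nm = 0) {
  enumerate_scenarios(
    list(density = c(50, 100, 200, 300, 400, 500),
         pct = seq(10, 90, by = 10),
         ppc = c(5, 10, 20, 50, 100),
         radius = seq(10, 100, by = 10)),
    cluster_model = cluster_model, axial_range_nm = axial_range_nm)
}

#' Novel evaluation scenario grid
#'
#' The out-of-training evaluation grid: percent clustered in
#' `{5, 10, ..., 100}` and cluster radius in `{5, 10, ..., 100}` nm,
#' crossed with four fixed (density, points-per-cluster) pairs:
#' (50, 10), (100, 20), (300, 100) and (500, 80), giving 484 scenarios.
#'
#' @inheritParams enumerate_scenarios
#' @return List of 484 `cluster_scenario` objects.
#' @export
novel_scenario_grid <- function(cluster_model = "uniform-disc",
                                axial_range_nm = 0) {
  pairs <- list(c(50, 10), c(100, 20), c(300, 100), c(500, 80))
  out <- list()
  for (pr in pairs) {
    out <- c(out, enumerate_scenarios(
      list(density = pr[1], pct = c(5, seq(10, 100, by = 10)),
           ppc = pr[2], radius = c(5, seq(10, 100, by = 10))),
      cluster_model = cluster_model, axial_range_nm = axial_range_nm))
  }
  out
}

#' Filter a scenario list to the viable subset
#'
#' @param scenarios List of `cluster_scenario`.
#' @param cell A `cell_shape` supplying the field area.
#' @return The scenarios for which [assess_viability()] returns `viable`.
#' @export
viable_scenarios <- function(scenarios, cell = generate_cell_shape()) {
  keep <- vapply(scenarios, function(s) {
    v <- tryCatch(assess_viability(s, cell), error = function(e) NULL)
    !is.null(v) && v$viable
  }, logical(1))
  scenarios[keep]
}
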