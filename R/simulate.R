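#' Simulate a ground-truth localization field
#'
#' Places points inside a cell-like boundary according to a clustering
#' scenario and returns both the localization table and the per-point
#' ground truth.  The total point count is the overall density times the
#' cell area (rounded half-up); the requested fraction of points is
#' distributed around uniformly placed cluster seeds, the remainder as
#' complete spatial randomness (CSR) inside the boundary.  The last
#' cluster may be under-filled so the clustered-point total is hit
#' exactly.
#'
#' Cluster models:
#' \describe{
#'   \item{uniform-disc}{uniform over the disc of radius
#'     `cluster_radius_nm` around the seed.}
#'   \item{gaussian}{isotropic normal with `sigma = cluster_radius_nm/2`,
#'     truncated at `2 sigma`, so ~95% of the untruncated mass lies within
#'     the nominal radius.}
#'   \item{fiber}{uniform along a bounded-turning random-walk polyline
#'     (default length 2 um, step 100 nm, turns within +/-30 degrees)
#'     with lateral normal jitter (sigma 20 nm).}
#'   \item{ring}{uniform on the annulus between
#'     `ring_fraction * cluster_radius_nm` and `cluster_radius_nm`.}
#'   \item{sphere-3d}{uniform in the 3D ball of radius
#'     `cluster_radius_nm`; all z coordinates (seeds and CSR background)
#'     are confined to `[0, axial_range_nm]`.}
#' }
#'
#' All points lie inside the cell polygon; cluster members falling
#' outside (seed near the boundary) are redrawn with a bounded retry
#' budget.  Fields are deterministic for a fixed seed.
#'
#' @param scenario A `cluster_scenario`.
#' @param cell A `cell_shape`.
#' @param seed Integer seed for this field.
#' @param check_viability If `TRUE` (default) refuse scenarios that fail
#'   [assess_viability()]; set `FALSE` for CSR controls, evaluation grids
#'   and stress tests.
#' @param fiber_length_nm,fiber_step_nm,fiber_max_turn_deg,fiber_jitter_nm
#'   Fiber-model knobs (see Details).
#' @param ring_fraction Inner/outer radius ratio of the ring model.
#' @return A list of class `sim_field` with `table` (data.frame
#'   `point_id`, `x`, `y`\[, `z`\] in nm), `truth` (data.frame `label`,
#'   `true_cluster_id`), `seed_positions` (matrix of cluster seeds),
#'   `scenario`, `cell`, `seed`.
#' @examples
#' f <- simulate_field(cluster_scenario(100, 50, 10, 30),
#'                     generate_cell_shape(1), seed = 2)
#' table(f$truth$label)
#' @export
simulate_field <- function(scenario, cell = generate_cell_shape(),
                           seed = 1L, check_viability = TRUE,
                           fiber_length_nm = 2000, fiber_step_nm = 100,
                           fiber_max_turn_deg = 30, fiber_jitter_nm = 20,
                           ring_fraction = 0.5) {
  stopifnot(inherits(scenario, "cluster_scenario"),
            inherits(cell, "cell_shape"))
  if (check_viability) {
    v <- assess_viability(scenario, cell)
    if (!v$viable)
      abort_param(paste0(
        "scenario is not viable (%.3g clusters/um^2, density ratio %.3g); ",
        "pass check_viability = FALSE to simulate it anyway"),
        v$clusters_per_um2, v$density_ratio)
  }
  dims <- if (scenario$cluster_model == "sphere-3d" ||
              scenario$axial_range_nm > 0) 3L else 2L

  withr_seed(seed, {
    n_total <- round_half_up(scenario$overall_density * cell$area_um2)
    n_clustered <- round_half_up(n_total * scenario$pct_clustered / 100)
    ppc <- scenario$points_per_cluster
    n_clusters <- if (n_clustered > 0) ceiling(n_clustered / ppc) else 0L

    seeds <- runif_in_cell(n_clusters, cell)
    if (dims == 3L && n_clusters > 0)
      seeds <- cbind(seeds, z = runif(n_clusters, 0, scenario$axial_range_nm))

    # per-cluster populations: full except possibly the last
    sizes <- if (n_clusters > 0) {
      s <- rep(ppc, n_clusters)
      s[n_clusters] <- n_clustered - ppc * (n_clusters - 1L)
      s
    } else integer(0)

    cpts <- vector("list", n_clusters)
    for (ci in seq_len(n_clusters)) {
      cpts[[ci]] <- place_cluster_points(
        sizes[ci], seeds[ci, ], scenario, cell, dims,
        fiber_length_nm, fiber_step_nm, fiber_max_turn_deg,
        fiber_jitter_nm, ring_fraction)
    }
    clustered <- if (n_clusters > 0) do.call(rbind, cpts) else
      matrix(numeric(0), 0, dims)
    cluster_id <- rep(seq_len(n_clusters), times = sizes)

    n_bg <- n_total - n_clustered
    bg <- runif_in_cell(n_bg, cell)
    if (dims == 3L) bg <- cbind(bg, z = runif(n_bg, 0, scenario$axial_range_nm))

    coords <- rbind(clustered, bg)
    lab <- c(rep(1L, n_clustered), rep(0L, n_bg))
    if (scenario$cluster_model == "fiber") lab[lab == 1L] <- 2L
    cid <- c(cluster_id, rep(0L, n_bg))

    # shuffle so file order carries no label information
    ord <- sample.int(n_total)
    coords <- coords[ord, , drop = FALSE]
    lab <- lab[ord]
    cid <- cid[ord]

    tab <- data.frame(point_id = seq_len(n_total),
                      x = coords[, 1], y = coords[, 2])
    if (dims == 3L) tab$z <- coords[, 3]
    structure(list(
      table = tab,
      truth = data.frame(label = lab, true_cluster_id = cid),
      seed_positions = seeds,
      scenario = scenario, cell = cell, seed = seed
    ), class = "sim_field")
  })
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("sim_field: %d points (%d clustered, %d clusters), seed %d\n",
              nrow(x$table), sum(x$truth$label > 0),
              nrow(x$seed_positions) %||% 0L, x$seed))
  print(x$scenario)
  invisible(x)
}

# Draw `n` cluster member points around `seed_pos` per the scenario's
# cluster model, rejecting draws that land outside the cell polygon.
place_cluster_points <- function(n, seed_pos, scenario, cell, dims,
                                 fiber_length_nm, fiber_step_nm,
                                 fiber_max_turn_deg, fiber_jitter_nm,
                                 ring_fraction, max_tries = 200L) {
  r <- scenario$cluster_radius_nm
  model <- scenario$cluster_model
  fiber_path <- NULL
  if (model == "fiber")
    fiber_path <- fiber_polyline(seed_pos[1:2], fiber_length_nm,
                                 fiber_step_nm, fiber_max_turn_deg)
  out <- matrix(NA_real_, n, dims)
  got <- 0L
  for (try in seq_len(max_tries)) {
    need <- n - got
    if (need == 0L) break
    m <- max(2L * need, 8L)
    cand <- switch(model,
      "uniform-disc" = {
        rr <- r * sqrt(runif(m)); th <- runif(m, 0, 2 * pi)
        cbind(seed_pos[1] + rr * cos(th), seed_pos[2] + rr * sin(th))
      },
      "gaussian" = {
        sg <- r / 2
        repeat {
          dx <- rnorm(m, 0, sg); dy <- rnorm(m, 0, sg)
          keep <- (dx^2 + dy^2) <= (2 * sg)^2
          if (any(keep)) break
        }
        cbind(seed_pos[1] + dx[keep], seed_pos[2] + dy[keep])
      },
      "ring" = {
        r0 <- ring_fraction * r
        rr <- sqrt(runif(m, r0^2, r^2)); th <- runif(m, 0, 2 * pi)
        cbind(seed_pos[1] + rr * cos(th), seed_pos[2] + rr * sin(th))
      },
      "fiber" = {
        pts <- sample_polyline(fiber_path, m)
        jit <- rnorm(m, 0, fiber_jitter_nm)
        # lateral jitter perpendicular to the local segment direction
        pts$xy + cbind(-sin(pts$ang) * jit, cos(pts$ang) * jit)
      },
      "sphere-3d" = {
        rr <- r * runif(m)^(1 / 3)
        u <- runif(m, -1, 1); phi <- runif(m, 0, 2 * pi)
        s <- sqrt(1 - u^2)
        cbind(seed_pos[1] + rr * s * cos(phi),
              seed_pos[2] + rr * s * sin(phi),
              seed_pos[3] + rr * u)
      })
    ok <- points_in_polygon(cand[, 1], cand[, 2], cell$vertices)
    if (dims == 3L && ncol(cand) == 3) {
      ok <- ok & cand[, 3] >= 0 & cand[, 3] <= scenario$axial_range_nm
    } else if (dims == 3L) {
      cand <- cbind(cand, seed_pos[3])
    }
    take <- min(sum(ok), need)
    if (take > 0) {
      sel <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cand[sel, seq_len(dims), drop = FALSE]
      got <- got + take
    }
  }
  if (got < n)
    stop(sprintf(
      "could not place %d cluster points inside the cell after %d tries",
      n, max_tries), call. = FALSE)
  out
}

# Bounded-turning random-walk polyline starting at `start`; returns the
# vertex matrix and per-segment angles.
fiber_polyline <- function(start, length_nm, step_nm, max_turn_deg) {
  n_steps <- max(1L, round_half_up(length_nm / step_nm))
  ang <- runif(1, 0, 2 * pi)
  verts <- matrix(NA_real_, n_steps + 1L, 2)
  verts[1, ] <- start
  angs <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    angs[i] <- ang
    verts[i + 1L, ] <- verts[i, ] +
      step_nm * c(cos(ang), sin(ang))
    ang <- ang + runif(1, -1, 1) * max_turn_deg * pi / 180
  }
  list(verts = verts, angs = angs)
}

# Uniform samples along a polyline's arclength.
sample_polyline <- function(path, m) {
  n_seg <- nrow(path$verts) - 1L
  seg <- sample.int(n_seg, m, replace = TRUE)  # equal-length segments
  t <- runif(m)
  xy <- path$verts[seg, , drop = FALSE] +
    t * (path$verts[seg + 1L, , drop = FALSE] - path$verts[seg, , drop = FALSE])
  list(xy = xy, ang = path$angs[seg])
}
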