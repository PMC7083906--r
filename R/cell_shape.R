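#' Generate an irregular cell-like boundary polygon
#'
#' Builds a star-shaped polygon emulating the gross morphology of a cell
#' synapse imaged against a flat surface (TIRF geometry): a circle whose
#' vertex radii are randomly perturbed and then smoothed, giving uneven,
#' protrusion-like edges.  All simulated localizations are confined to
#' this boundary.
#'
#' Vertex radii are drawn uniformly from
#' `mean_diameter_um/2 * [1 - irregularity, 1 + irregularity]` and passed
#' through a circular 3-vertex moving average, so the polygon is always
#' simple (star-shaped about its centre).
#'
#' @param seed Integer seed; the polygon is deterministic given the seed.
#' @param mean_diameter_um Mean cell diameter in micrometres (> 0).
#' @param irregularity Fractional radial perturbation in `[0, 1]`.
#'   `0` gives a regular polygon.
#' @param n_vertices Number of boundary vertices (>= 8).
#' @return An object of class `cell_shape` with elements `vertices`
#'   (closed `n+1` x 2 matrix, nm), `area_um2`, and the generating
#'   parameters.
#' @examples
#' cell <- generate_cell_shape(seed = 1)
#' cell$area_um2
#' @export
generate_cell_shape <- function(seed = 1L, mean_diameter_um = 10,
                                irregularity = 0.25, n_vertices = 64L) {
  if (!is.finite(mean_diameter_um) || mean_diameter_um <= 0)
    abort_param("mean_diameter_um must be positive, got %s", mean_diameter_um)
  if (!is.finite(irregularity) || irregularity < 0 || irregularity > 1)
    abort_param("irregularity must lie in [0, 1], got %s", irregularity)
  if (n_vertices < 8)
    abort_param("n_vertices must be >= 8, got %d", n_vertices)

  r0 <- mean_diameter_um / 2 * 1000  # nm
  radii <- withr_seed(seed, {
    r0 * runif(n_vertices, 1 - irregularity, 1 + irregularity)
  })
  # circular 3-vertex moving average keeps the outline cell-like rather
  # than jagged
  prv <- c(radii[n_vertices], radii[-n_vertices])
  nxt <- c(radii[-1], radii[1])
  smoothed <- (prv + radii + nxt) / 3

  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  verts <- cbind(x = smoothed * cos(theta), y = smoothed * sin(theta))
  closed <- rbind(verts, verts[1, , drop = FALSE])

  structure(list(
    vertices = closed,
    area_um2 = polygon_area(verts) / 1e6,
    mean_diameter_um = mean_diameter_um,
    irregularity = irregularity,
    n_vertices = n_vertices,
    seed = seed
  ), class = "cell_shape")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf(
    "cell_shape: %d vertices, mean diameter %.1f um, irregularity %.2f, area %.2f um^2\n",
    x$n_vertices, x$mean_diameter_um, x$irregularity, x$area_um2))
  invisible(x)
}

#' Bounding box of a cell shape (nm)
#' @param cell A `cell_shape`.
#' @return Named list `xmin`, `xmax`, `ymin`, `ymax`.
#' @keywords internal
cell_bbox <- function(cell) {
  v <- cell$vertices
  list(xmin = min(v[, 1]), xmax = max(v[, 1]),
       ymin = min(v[, 2]), ymax = max(v[, 2]))
}

# Uniform points inside the cell polygon by rejection from the bounding
# box.  Assumes the current RNG state; callers own seeding.
runif_in_cell <- function(n, cell, max_tries = 1000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  bb <- cell_bbox(cell)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  for (i in seq_len(max_tries)) {
    need <- n - got
    m <- max(need * 2L, 16L)
    px <- runif(m, bb$xmin, bb$xmax)
    py <- runif(m, bb$ymin, bb$ymax)
    ok <- points_in_polygon(px, py, cell$vertices)
    take <- min(sum(ok), need)
    if (take > 0) {
      sel <- which(ok)[seq_len(take)]
      out[got + seq_len(take), ] <- cbind(px[sel], py[sel])
      got <- got + take
    }
    if (got == n) break
  }
  if (got < n)
    stop("rejection sampling inside the cell polygon failed; boundary may be degenerate",
         call. = FALSE)
  colnames(out) <- c("x", "y")
  out
}
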