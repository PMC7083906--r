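#' Partition clustered points into discrete clusters
#'
#' Implements nearest-neighbour chaining with a walk-and-stop rule: for
#' each point labelled clustered, its neighbours are visited in
#' increasing-distance order and every clustered neighbour is added to
#' the point's group until the first non-clustered neighbour is
#' encountered.  Groups sharing members are merged (union-find) into the
#' final clusters; clusters smaller than `min_cluster_size` are demoted
#' to the unclustered pool (`cluster_id = 0`).
#'
#' The walk reuses the k-NN structure computed during featurization and
#' is therefore capped at `k` neighbours per point, matching the "reach"
#' of a model with input window `k`.  Distance ties are broken by point
#' id, so the segmentation is deterministic.
#'
#' @param table Localization data.frame (`x`, `y`\[, `z`\] in nm).
#' @param labels A `point_labels` object from [classify_points()], or an
#'   integer vector of 0/1 (or 0/1/2) labels aligned with `table` rows
#'   (ground-truth labels work directly).
#' @param min_cluster_size Minimum member count for a reported cluster
#'   (default 3; pairs and singletons are geometrically degenerate for
#'   shape building).
#' @param knn Optional `feature_matrix` from [knn_distances()] whose
#'   neighbour index matrix is reused; computed at `k` when absent.
#' @param k Neighbour cap when `knn` is not supplied (default 100).
#' @return An object of class `cluster_assignment`: `cluster_id`
#'   (per-point integer, 0 = unassigned), `clusters` (named list id ->
#'   member row indices), `labels` (the input hard labels) and
#'   `min_cluster_size`.
#' @examples
#' tab <- data.frame(x = c(0, 10, 20, 500, 600), y = 0)
#' seg <- segment_points(tab, c(1, 1, 1, 0, 1), min_cluster_size = 2, k = 4)
#' seg$cluster_id
#' @export
segment_points <- function(table, labels, min_cluster_size = 3L,
                           knn = NULL, k = 100L) {
  lab <- if (inherits(labels, "point_labels")) labels$label else
    as.integer(labels)
  n <- nrow(table)
  if (length(lab) != n)
    abort_param("labels length %d does not align with %d table rows",
                length(lab), n)
  if (is.null(knn)) {
    k <- min(as.integer(k), n - 1L)
    knn <- knn_distances(table, k)
  }
  idx <- knn$idx
  clustered <- lab > 0L

  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (i in which(clustered)) {
    for (j in idx[i, ]) {
      if (!clustered[j]) break  # stop at the first non-clustered neighbour
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }

  cluster_id <- integer(n)
  roots <- vapply(which(clustered), find, integer(1))
  groups <- split(which(clustered), roots)
  keep <- groups[lengths(groups) >= min_cluster_size]
  # stable ids: order clusters by smallest member index
  if (length(keep)) {
    keep <- keep[order(vapply(keep, min, integer(1)))]
    names(keep) <- seq_along(keep)
    for (ci in seq_along(keep)) cluster_id[keep[[ci]]] <- ci
  }
  structure(list(cluster_id = cluster_id, clusters = keep,
                 labels = lab, min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: %d clusters over %d clustered points (%d demoted)\n",
    length(x$clusters), sum(x$labels > 0),
    sum(x$labels > 0 & x$cluster_id == 0)))
  invisible(x)
}

#' Build a disc-union cluster outline shape
#'
#' Centres a disc on every member point — the disc radius proportional
#' to the members' mean nearest-neighbour distance — takes the union of
#' all discs, and erodes the union inward, again proportionally to the
#' mean nearest-neighbour distance.  The outline is extracted by
#' contouring the erosion's exact distance-field characterization on a
#' fine grid, so the reported area equals the polygon area by
#' construction.
#'
#' If erosion annihilates the shape entirely, the un-eroded disc union
#' is returned and flagged (`eroded_away = TRUE`).  Erosion may split a
#' shape into disjoint parts; all parts belong to the same cluster and
#' their areas are summed (`n_parts` reports the count).
#'
#' @param members Matrix or data.frame of member coordinates (nm); only
#'   x and y are used for the outline (3D clusters are reported as their
#'   2D projection).
#' @param disc_factor Disc radius as a multiple of mean NND (default 1).
#' @param erosion_factor Erosion depth as a multiple of mean NND
#'   (default 0.5).
#' @param default_nnd_nm Stand-in for the mean NND when the cluster has
#'   a single member (default 20 nm).
#' @param grid_n Grid nodes across the disc radius (default 24; higher
#'   is finer).
#' @return An object of class `cluster_shape`: `polygons` (list of
#'   closed vertex matrices; holes carry negative signed area),
#'   `area_nm2`, `mean_nnd_nm`, `disc_radius_nm`, `erosion_nm`,
#'   `eroded_away`, `n_parts`.
#' @examples
#' sh <- build_cluster_shape(cbind(c(0, 30), c(0, 0)))
#' sh$area_nm2
#' @export
build_cluster_shape <- function(members, disc_factor = 1,
                                erosion_factor = 0.5,
                                default_nnd_nm = 20, grid_n = 24L) {
  members <- as.matrix(members)
  if (nrow(members) == 0) abort_param("empty member set")
  pts <- members[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"

  mean_nnd <- if (nrow(pts) >= 2) {
    full <- members[, seq_len(min(ncol(members), 3)), drop = FALSE]
    storage.mode(full) <- "double"
    mean(.knn_brute_cpp(full, 1L)$dist[, 1])
  } else default_nnd_nm
  r <- disc_factor * mean_nnd
  e <- erosion_factor * mean_nnd
  if (r <= 0) abort_param("disc radius must be positive")

  shape <- shape_from_field(pts, r, e, grid_n)
  eroded_away <- FALSE
  if (length(shape$polygons) == 0 && e > 0) {
    shape <- shape_from_field(pts, r, 0, grid_n)
    eroded_away <- TRUE
  }
  structure(list(polygons = shape$polygons, area_nm2 = shape$area,
                 mean_nnd_nm = mean_nnd, disc_radius_nm = r,
                 erosion_nm = if (eroded_away) 0 else e,
                 eroded_away = eroded_away,
                 n_parts = shape$n_parts),
            class = "cluster_shape")
}

# Contour the eroded disc union.  The eroded set is exactly
# {p : max_{|u|<=e} dist(p+u, members) <= r}; the field is Lipschitz-1 so
# linear interpolation by contourLines is sub-grid accurate.
shape_from_field <- function(pts, r, e, grid_n, max_nodes = 4e6) {
  h <- r / grid_n
  pad <- r + e + 2 * h
  ext <- c(diff(range(pts[, 1])), diff(range(pts[, 2]))) + 2 * pad
  if (prod(ext / h) > max_nodes) h <- sqrt(prod(ext) / max_nodes)
  gx <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, by = h)
  gy <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, by = h)
  dt <- .dilated_distance_field_cpp(pts, gx, gy, e)
  cl <- grDevices::contourLines(gx, gy, r - dt, levels = 0)
  if (length(cl) == 0) return(list(polygons = list(), area = 0, n_parts = 0L))
  polys <- lapply(cl, function(p) cbind(x = p$x, y = p$y))
  # hole depth: number of other loops strictly containing this loop
  depth <- vapply(seq_along(polys), function(i) {
    v <- polys[[i]][1, ]
    sum(vapply(seq_along(polys), function(j) {
      if (j == i) return(FALSE)
      as.logical(points_in_polygon(v[1], v[2], polys[[j]]))
    }, logical(1)))
  }, numeric(1))
  signed <- vapply(polys, function(p) abs(polygon_area_signed(p)),
                   numeric(1))
  area <- sum(ifelse(depth %% 2 == 0, signed, -signed))
  list(polygons = polys, area = area,
       n_parts = sum(depth %% 2 == 0))
}

#' @export
print.cluster_shape <- function(x, ...) {
  cat(sprintf(
    "cluster_shape: area %.0f nm^2, mean NND %.1f nm, %d part(s)%s\n",
    x$area_nm2, x$mean_nnd_nm, x$n_parts,
    if (x$eroded_away) " [erosion annihilated; un-eroded union reported]"
    else ""))
  invisible(x)
}

#' Build outline shapes for every reported cluster
#'
#' @param table The localization table used for segmentation.
#' @param assignment A `cluster_assignment`.
#' @inheritParams build_cluster_shape
#' @return Named list of `cluster_shape`, one per reported cluster.
#' @export
cluster_shapes <- function(table, assignment, disc_factor = 1,
                           erosion_factor = 0.5, default_nnd_nm = 20,
                           grid_n = 24L) {
  cols <- intersect(c("x", "y", "z"), names(table))
  coords <- as.matrix(table[, cols, drop = FALSE])
  out <- lapply(assignment$clusters, function(ix)
    build_cluster_shape(coords[ix, , drop = FALSE], disc_factor,
                        erosion_factor, default_nnd_nm, grid_n))
  names(out) <- names(assignment$clusters)
  out
}

#' Summarize a segmented field
#'
#' @param assignment A `cluster_assignment`.
#' @param shapes List of `cluster_shape` covering exactly the reported
#'   clusters (as from [cluster_shapes()]).
#' @param analysis_area_um2 Area over which cluster density is reported
#'   (e.g. the cell area or the convex hull from [hull_area_um2()]).
#' @return An object of class `cluster_stats`: `n_clusters`,
#'   `clusters_per_um2`, `pct_points_clustered`, and per-cluster counts
#'   and areas with their medians and IQRs.
#' @export
summarize_clusters <- function(assignment, shapes, analysis_area_um2) {
  if (analysis_area_um2 <= 0) abort_param("analysis_area_um2 must be positive")
  ids <- names(assignment$clusters)
  if (!setequal(names(shapes), ids))
    abort_param("shapes must cover exactly the reported clusters")
  shapes <- shapes[ids]
  n_pts <- length(assignment$cluster_id)
  counts <- lengths(assignment$clusters)
  areas <- vapply(shapes, function(s) s$area_nm2, numeric(1))
  iqr <- function(v) if (length(v)) unname(quantile(v, c(0.25, 0.75)))
                     else c(NA_real_, NA_real_)
  structure(list(
    n_clusters = length(ids),
    clusters_per_um2 = length(ids) / analysis_area_um2,
    pct_points_clustered = 100 * sum(counts) / n_pts,
    points_per_cluster = as.numeric(counts),
    median_points_per_cluster = if (length(counts)) median(counts) else NA_real_,
    iqr_points_per_cluster = iqr(as.numeric(counts)),
    cluster_area_nm2 = unname(areas),
    median_cluster_area_nm2 = if (length(areas)) median(areas) else NA_real_,
    iqr_cluster_area_nm2 = iqr(areas),
    analysis_area_um2 = analysis_area_um2
  ), class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    paste0("cluster_stats: %.2f clusters/um^2 (%d clusters), ",
           "%.1f%% of points clustered\n",
           "  points/cluster: median %s (IQR %s-%s); ",
           "area: median %s nm^2 (IQR %s-%s)\n"),
    x$clusters_per_um2, x$n_clusters, x$pct_points_clustered,
    format(x$median_points_per_cluster),
    format(x$iqr_points_per_cluster[1]), format(x$iqr_points_per_cluster[2]),
    format(round(x$median_cluster_area_nm2)),
    format(round(x$iqr_cluster_area_nm2[1])),
    format(round(x$iqr_cluster_area_nm2[2]))))
  invisible(x)
}

#' Convex-hull analysis area of a localization table
#'
#' @param table Localization data.frame with `x`, `y` in nm.
#' @return Hull area in square micrometres.
#' @export
hull_area_um2 <- function(table) {
  hp <- grDevices::chull(table$x, table$y)
  polygon_area(cbind(table$x[hp], table$y[hp])) / 1e6
}

#' Export cluster outlines as WKT polygons
#'
#' @param shapes List of `cluster_shape`.
#' @return Character vector, one `POLYGON`/`MULTIPOLYGON` per cluster.
#' @export
shapes_wkt <- function(shapes) {
  vapply(shapes, function(s) {
    rings <- vapply(s$polygons, function(p) {
      q <- rbind(p, p[1, ])
      paste0("(", paste(sprintf("%.2f %.2f", q[, 1], q[, 2]),
                        collapse = ", "), ")")
    }, character(1))
    if (length(rings) == 1) paste0("POLYGON (", rings, ")")
    else paste0("MULTIPOLYGON ((", paste(rings, collapse = "), ("), "))")
  }, character(1))
}
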