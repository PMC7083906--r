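# Shared toy constructions used across test files.

# A linearly separable pool: "clustered" rows are the same sorted-uniform
# sequences compressed by 10x, mimicking the compressed early NN
# distances of a clustered point.
toy_separable_pool <- function(n, k = 100L, seed = 1L, split = "train") {
  set.seed(seed)
  base <- t(apply(matrix(runif(n * k), n), 1, sort))
  cl <- sample(c(0L, 1L), n, replace = TRUE)
  structure(list(features = base * ifelse(cl == 1L, 0.1, 1),
                 labels = cl, split = split, k = as.integer(k),
                 representation = "distance"),
            class = "labeled_pool")
}

# Small shared cell used by many tests (area ~85 um^2).
test_cell <- function() generate_cell_shape(seed = 42)

# Brute-force kNN oracle via dist(): returns the n x k sorted distance
# matrix, computed independently of the package's C++ search.
knn_oracle <- function(coords, k) {
  dm <- as.matrix(dist(coords))
  diag(dm) <- Inf
  t(apply(dm, 1, function(r) sort(r)[seq_len(k)]))
}

# Area of the union of two discs of radius r whose centres are d apart
# (closed form via the lens area of the intersection).
two_disc_union_area <- function(r, d) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# Adjusted Rand index between two integer labelings (mclust when
# available, otherwise the standard pair-counting formula).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab))); n2 <- ch2(sum(tab))
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}

# A constructed well-separated field: 30 clusters of 10 points in 30 nm
# discs on a 1.5 um grid, CSR background (~40/um^2) kept outside a
# 200 nm halo around every centre.  Separation is guaranteed, so
# walk-and-stop segmentation with perfect labels must recover the
# partition exactly.
separated_field <- function(seed, n_side = c(6, 5), spacing = 1500,
                            r = 30, ppc = 10, halo = 200, bg_per_um2 = 40) {
  set.seed(seed)
  cx <- rep(seq_len(n_side[1]) - 1, n_side[2]) * spacing
  cy <- rep(seq_len(n_side[2]) - 1, each = n_side[1]) * spacing
  nc <- length(cx)
  th <- runif(nc * ppc, 0, 2 * pi)
  rr <- r * sqrt(runif(nc * ppc))
  mx <- rep(cx, each = ppc) + rr * cos(th)
  my <- rep(cy, each = ppc) + rr * sin(th)
  lo <- -spacing / 2
  hix <- (n_side[1] - 0.5) * spacing; hiy <- (n_side[2] - 0.5) * spacing
  nbg <- round(bg_per_um2 * (hix - lo) * (hiy - lo) / 1e6)
  bx <- runif(nbg, lo, hix); by <- runif(nbg, lo, hiy)
  ok <- rep(TRUE, nbg)
  for (i in seq_len(nc))
    ok <- ok & ((bx - cx[i])^2 + (by - cy[i])^2 > halo^2)
  list(tab = data.frame(x = c(mx, bx[ok]), y = c(my, by[ok])),
       label = c(rep(1L, nc * ppc), rep(0L, sum(ok))),
       true_id = c(rep(seq_len(nc), each = ppc), rep(0L, sum(ok))))
}

# Independent oracle for the disc-union-erode construction, in plain R.
# A point p lies in the eroded union iff the whole disc of radius e
# around p lies within distance r of some member; since the distance
# field has no interior local maxima that is equivalent to
#   max over the circle |u| = e of dist(p + u, members) <= r.
# Unlike the package implementation, distances at the sampled circle
# positions are computed exactly (no interpolated grid field).
raster_shape_area <- function(pts, r, e, h = NULL, na = 180L) {
  if (is.null(h)) h <- r / 40
  pad <- r + e + 2 * h
  gx <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, by = h)
  gy <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, by = h)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  dist_to_members <- function(qx, qy) {
    best <- rep(Inf, length(qx))
    for (i in seq_len(nrow(pts)))
      best <- pmin(best, (qx - pts[i, 1])^2 + (qy - pts[i, 2])^2)
    sqrt(best)
  }
  if (e > 0) {
    worst <- rep(-Inf, length(px))
    for (a in 2 * pi * seq_len(na) / na)
      worst <- pmax(worst, dist_to_members(px + e * cos(a),
                                           py + e * sin(a)))
  } else worst <- dist_to_members(px, py)
  fld <- matrix(r - worst, length(gx), length(gy))
  cl <- grDevices::contourLines(gx, gy, fld, levels = 0)
  shoelace <- function(p) {
    n <- length(p$x)
    abs(sum(p$x * p$y[c(2:n, 1)] - p$x[c(2:n, 1)] * p$y)) / 2
  }
  in_poly <- function(x, y, p) {
    j <- length(p$x); inside <- FALSE
    for (i in seq_along(p$x)) {
      if ((p$y[i] > y) != (p$y[j] > y) &&
          x < (p$x[j] - p$x[i]) * (y - p$y[i]) / (p$y[j] - p$y[i]) + p$x[i])
        inside <- !inside
      j <- i
    }
    inside
  }
  depth <- vapply(seq_along(cl), function(i) {
    sum(vapply(seq_along(cl), function(j)
      j != i && in_poly(cl[[i]]$x[1], cl[[i]]$y[1], cl[[j]]), logical(1)))
  }, numeric(1))
  sum(ifelse(depth %% 2 == 0, 1, -1) * vapply(cl, shoelace, numeric(1)))
}
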