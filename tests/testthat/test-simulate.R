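test_that("pure CSR field has the right count and all-zero labels", {
  cell <- test_cell()
  sc <- cluster_scenario(100, 0, 10, 30)
  f <- simulate_field(sc, cell, seed = 5, check_viability = FALSE)
  expect_equal(nrow(f$table), round(100 * cell$area_um2))
  expect_true(all(f$truth$label == 0))
  expect_true(all(f$truth$true_cluster_id == 0))
})

test_that("fully clustered field has ceiling(n/ppc) clusters, all labeled", {
  cell <- test_cell()
  sc <- cluster_scenario(50, 100, 10, 50)
  f <- simulate_field(sc, cell, seed = 9, check_viability = FALSE)
  n <- nrow(f$table)
  expect_true(all(f$truth$true_cluster_id > 0))
  expect_true(all(f$truth$label == 1))
  expect_equal(length(unique(f$truth$true_cluster_id)), ceiling(n / 10))
})

test_that("label bookkeeping matches pct_clustered within one cluster", {
  cell <- test_cell()
  sc <- cluster_scenario(100, 30, 10, 40)
  f <- simulate_field(sc, cell, seed = 2)
  n <- nrow(f$table)
  expect_lte(abs(sum(f$truth$label == 1) / n - 0.30),
             sc$points_per_cluster / n)
  # label/true_cluster_id consistency
  expect_true(all(f$truth$label[f$truth$true_cluster_id > 0] >= 1))
  expect_true(all(f$truth$true_cluster_id[f$truth$label == 0] == 0))
})

test_that("uniform-disc members stay within the radius and follow the r^2 law", {
  cell <- test_cell()
  sc <- cluster_scenario(300, 90, 50, 60)
  f <- simulate_field(sc, cell, seed = 3, check_viability = FALSE)
  cid <- f$truth$true_cluster_id
  seeds <- f$seed_positions
  d <- sqrt((f$table$x - seeds[pmax(cid, 1), 1])^2 +
              (f$table$y - seeds[pmax(cid, 1), 2])^2)[cid > 0]
  expect_true(all(d <= sc$cluster_radius_nm + 1e-9))
  # Kolmogorov-Smirnov against the r^2-law CDF (uniform disc)
  ks <- suppressWarnings(
    ks.test(d, function(q) pmin(1, (q / sc$cluster_radius_nm)^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical density is within 2% of target and points in cell", {
  cell <- test_cell()
  sc <- cluster_scenario(200, 50, 10, 30)
  f <- simulate_field(sc, cell, seed = 8, check_viability = FALSE)
  dens <- nrow(f$table) / cell$area_um2
  expect_lt(abs(dens - 200) / 200, 0.02)
  ok <- smlmclust:::points_in_polygon(f$table$x, f$table$y, cell$vertices)
  expect_true(all(ok))
})

test_that("CSR field passes a quadrat-count chi-square uniformity test", {
  cell <- generate_cell_shape(seed = 11, irregularity = 0)  # disc cell
  sc <- cluster_scenario(130, 0, 10, 30)  # ~10^4 points
  f <- simulate_field(sc, cell, seed = 4, check_viability = FALSE)
  # 25 quadrats inscribed in the central square of the disc (side r*sqrt(2))
  s <- 5000 * sqrt(2)
  keep <- abs(f$table$x) < s / 2 & abs(f$table$y) < s / 2
  qx <- findInterval(f$table$x[keep], seq(-s / 2, s / 2, length.out = 6),
                     rightmost.closed = TRUE)
  qy <- findInterval(f$table$y[keep], seq(-s / 2, s / 2, length.out = 6),
                     rightmost.closed = TRUE)
  counts <- as.vector(table(factor(qx, 1:5), factor(qy, 1:5)))
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("fields are deterministic per seed and differ across seeds", {
  cell <- test_cell()
  sc <- cluster_scenario(100, 50, 10, 30)
  a <- simulate_field(sc, cell, seed = 21)
  b <- simulate_field(sc, cell, seed = 21)
  c <- simulate_field(sc, cell, seed = 22)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$table, c$table))
})

test_that("non-viable scenarios are refused unless explicitly unfiltered", {
  cell <- test_cell()
  sc <- cluster_scenario(50, 10, 10, 100)  # 0.5 clusters/um^2
  expect_error(simulate_field(sc, cell, seed = 1), "not viable")
  f <- simulate_field(sc, cell, seed = 1, check_viability = FALSE)
  expect_s3_class(f, "sim_field")
})

test_that("gaussian clusters truncate at 2 sigma = cluster radius", {
  cell <- test_cell()
  sc <- cluster_scenario(200, 80, 50, 60, cluster_model = "gaussian")
  f <- simulate_field(sc, cell, seed = 6, check_viability = FALSE)
  cid <- f$truth$true_cluster_id
  d <- sqrt((f$table$x - f$seed_positions[pmax(cid, 1), 1])^2 +
              (f$table$y - f$seed_positions[pmax(cid, 1), 2])^2)[cid > 0]
  expect_true(all(d <= sc$cluster_radius_nm + 1e-9))
  # tighter concentration than the uniform disc: mean well under r/2
  expect_lt(mean(d), 0.6 * sc$cluster_radius_nm)
})

test_that("ring clusters occupy the annulus only", {
  cell <- test_cell()
  sc <- cluster_scenario(200, 80, 50, 60, cluster_model = "ring")
  f <- simulate_field(sc, cell, seed = 6, check_viability = FALSE)
  cid <- f$truth$true_cluster_id
  d <- sqrt((f$table$x - f$seed_positions[pmax(cid, 1), 1])^2 +
              (f$table$y - f$seed_positions[pmax(cid, 1), 2])^2)[cid > 0]
  expect_true(all(d <= 60 + 1e-9))
  expect_true(all(d >= 30 - 1e-9))
})

test_that("fiber clusters get label 2 and elongated extent", {
  cell <- test_cell()
  sc <- cluster_scenario(100, 50, 100, 50, cluster_model = "fiber")
  f <- simulate_field(sc, cell, seed = 13, check_viability = FALSE)
  expect_setequal(unique(f$truth$label), c(0L, 2L))
  # a fiber's bounding-box diagonal far exceeds its nominal radius
  one <- f$truth$true_cluster_id == 1
  ext <- sqrt(diff(range(f$table$x[one]))^2 + diff(range(f$table$y[one]))^2)
  expect_gt(ext, 4 * sc$cluster_radius_nm)
})

test_that("3D spherical fields confine z to the axial range", {
  cell <- test_cell()
  sc <- cluster_scenario(100, 50, 10, 50, cluster_model = "sphere-3d",
                         axial_range_nm = 500)
  f <- simulate_field(sc, cell, seed = 10)
  expect_true(!is.null(f$table$z))
  expect_true(all(f$table$z >= 0 & f$table$z <= 500))
  cid <- f$truth$true_cluster_id
  d3 <- sqrt((f$table$x - f$seed_positions[pmax(cid, 1), 1])^2 +
               (f$table$y - f$seed_positions[pmax(cid, 1), 2])^2 +
               (f$table$z - f$seed_positions[pmax(cid, 1), 3])^2)[cid > 0]
  expect_true(all(d3 <= sc$cluster_radius_nm + 1e-9))
})

test_that("output order carries no label information (shuffled)", {
  cell <- test_cell()
  sc <- cluster_scenario(100, 50, 10, 30)
  f <- simulate_field(sc, cell, seed = 30)
  lab <- f$truth$label
  # clustered points must not all sit at the front of the table
  first_half <- mean(lab[seq_len(length(lab) %/% 2)])
  expect_lt(abs(first_half - 0.5), 0.1)
})
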