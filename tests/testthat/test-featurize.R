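test_that("collinear hand example gives [3, 4] for the middle point", {
  tab <- data.frame(x = c(0, 3, 7), y = 0)
  fm <- knn_distances(tab, k = 2)
  expect_equal(fm$values[2, ], c(3, 4))
  expect_equal(fm$values[1, ], c(3, 7))
  expect_equal(fm$values[3, ], c(4, 7))
  expect_equal(fm$representation, "distance")
})

test_that("insufficient points raise an error naming n and k", {
  tab <- data.frame(x = c(0, 1), y = 0)
  expect_error(knn_distances(tab, k = 2), "n = 2.*k = 2")
})

test_that("knn_distances matches the brute-force oracle in 2D and 3D", {
  set.seed(101)
  tab2 <- data.frame(x = runif(200, 0, 1000), y = runif(200, 0, 1000))
  fm2 <- knn_distances(tab2, k = 50)
  expect_equal(fm2$values, knn_oracle(cbind(tab2$x, tab2$y), 50),
               tolerance = 1e-12, ignore_attr = TRUE)
  tab3 <- data.frame(x = runif(150, 0, 500), y = runif(150, 0, 500),
                     z = runif(150, 0, 500))
  fm3 <- knn_distances(tab3, k = 30)
  expect_equal(fm3$dims, 3L)
  expect_equal(fm3$values, knn_oracle(cbind(tab3$x, tab3$y, tab3$z), 30),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("distance rows are sorted non-decreasing and positive", {
  set.seed(7)
  tab <- data.frame(x = runif(300, 0, 2000), y = runif(300, 0, 2000))
  fm <- knn_distances(tab, k = 40)
  expect_true(all(fm$values > 0))
  expect_true(all(fm$values[, -1] - fm$values[, -40] >= 0))
})

test_that("CSR mean 1st-NN distance matches 1/(2 sqrt(lambda))", {
  cell <- generate_cell_shape(seed = 11, irregularity = 0)
  f <- simulate_field(cluster_scenario(130, 0, 10, 30), cell, seed = 44,
                      check_viability = FALSE)
  fm <- knn_distances(f$table, k = 1)
  # interior points only, to avoid boundary bias
  r_int <- sqrt(f$table$x^2 + f$table$y^2)
  keep <- r_int < 4000
  lambda <- 130 / 1e6  # per nm^2
  expected <- 1 / (2 * sqrt(lambda))
  se <- sqrt((4 - pi) / (4 * pi * lambda)) / sqrt(sum(keep))
  expect_lt(abs(mean(fm$values[keep, 1]) - expected), 3 * se)
})

test_that("to_differences is the inverse of cumulative sum", {
  expect_equal(
    to_differences(structure(list(values = matrix(c(3, 4), 1), k = 2L,
                                  dims = 2L, representation = "distance"),
                             class = "feature_matrix"))$values[1, ],
    c(3, 1))
  set.seed(5)
  tab <- data.frame(x = runif(100, 0, 500), y = runif(100, 0, 500))
  fm <- knn_distances(tab, k = 20)
  df <- to_differences(fm)
  expect_true(all(df$values >= 0))
  expect_equal(t(apply(df$values, 1, cumsum)), fm$values,
               tolerance = 1e-12)
  # arithmetic row maps to a constant row
  lat <- structure(list(values = matrix(seq(2, 20, by = 2), 1), k = 10L,
                        dims = 2L, representation = "distance"),
                   class = "feature_matrix")
  expect_equal(to_differences(lat)$values[1, ], rep(2, 10))
  expect_error(to_differences(df), "representation")
})

test_that("normalization ends rows at 1 and is density-scale invariant", {
  nrm <- to_normalized(structure(
    list(values = matrix(c(3, 4), 1), k = 2L, dims = 2L,
         representation = "distance"), class = "feature_matrix"))
  expect_equal(nrm$values[1, ], c(0.75, 1))
  set.seed(6)
  tab <- data.frame(x = runif(200, 0, 1000), y = runif(200, 0, 1000))
  a <- to_normalized(knn_distances(tab, k = 30))
  expect_true(all(a$values[, 30] == 1))
  expect_true(all(a$values > 0 & a$values <= 1))
  b <- to_normalized(knn_distances(transform(tab, x = 10 * x, y = 10 * y),
                                   k = 30))
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_error(to_normalized(a), "representation")
})

test_that("normalization rejects degenerate all-coincident rows", {
  fm <- structure(list(values = matrix(c(0, 0, 1, 2), 2, byrow = TRUE),
                       k = 2L, dims = 2L, representation = "distance"),
                  class = "feature_matrix")
  expect_error(to_normalized(fm), "degenerate")
})

test_that("build_training_pool balances, disjoins and reproduces", {
  set.seed(9)
  mk <- function(n, lab_frac) {
    v <- matrix(runif(n * 10), n)
    list(features = list(values = v, k = 10L,
                         representation = "distance"),
         truth = data.frame(label = rbinom(n, 1, lab_frac)))
  }
  ds <- list(mk(60, 0.5), mk(60, 0.5))
  pools <- build_training_pool(ds, 40, 20, 20, balance = TRUE, seed = 4)
  for (s in c("train", "val", "test")) {
    p <- pools[[s]]
    tb <- table(p$labels)
    expect_lte(abs(tb[["0"]] - tb[["1"]]), 1)
  }
  expect_equal(nrow(pools$train$features), 40)
  expect_equal(nrow(pools$val$features), 20)
  expect_equal(nrow(pools$test$features), 20)
  # disjointness via row fingerprints (rows are iid uniforms, a.s. unique)
  fp <- function(p) apply(p$features, 1, function(r) paste(r, collapse = ","))
  expect_length(intersect(fp(pools$train), fp(pools$val)), 0)
  expect_length(intersect(fp(pools$train), fp(pools$test)), 0)
  expect_length(intersect(fp(pools$val), fp(pools$test)), 0)
  # determinism
  again <- build_training_pool(ds, 40, 20, 20, balance = TRUE, seed = 4)
  expect_identical(pools$train$features, again$train$features)
  expect_identical(pools$train$labels, again$train$labels)
})

test_that("small exhaustive balanced split works and errors when short", {
  set.seed(2)
  v <- matrix(runif(20 * 5), 20)
  ds <- list(list(features = list(values = v, k = 5L,
                                  representation = "distance"),
                  truth = data.frame(label = rep(c(0L, 1L), 10))))
  pools <- build_training_pool(ds, 4, 2, 2, balance = TRUE, seed = 1)
  expect_equal(as.vector(table(pools$train$labels)), c(2, 2))
  expect_equal(as.vector(table(pools$val$labels)), c(1, 1))
  expect_error(build_training_pool(ds, 30, 2, 2, balance = TRUE, seed = 1),
               "insufficient")
})

test_that("feature container round-trips values, idx and header", {
  set.seed(3)
  tab <- data.frame(x = runif(80, 0, 500), y = runif(80, 0, 500))
  fm <- to_normalized(knn_distances(tab, k = 12))
  path <- tempfile(fileext = ".knn")
  on.exit(unlink(path))
  write_features(fm, path)
  back <- read_features(path)
  expect_identical(back$values, fm$values)
  expect_identical(back$idx, fm$idx)
  expect_equal(back$k, 12L)
  expect_equal(back$representation, "normalized-distance")
  bogus <- tempfile(fileext = ".knn")
  writeLines("{\"format\": \"something-else\"}", bogus)
  on.exit(unlink(bogus), add = TRUE)
  expect_error(read_features(bogus), "not a feature container")
})
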