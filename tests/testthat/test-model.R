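test_that("model presets match their published topology summaries", {
  x <- model_preset("XPILJZ")
  expect_equal(x$input_k, 100L)
  expect_equal(n_layers(x), 4L)    # input + dense + dense + output
  expect_equal(x$n_classes, 2L)

  b <- model_preset("87B144")
  expect_equal(b$input_k, 1000L)
  expect_equal(n_layers(b), 12L)
  v <- model_preset("07VEJJ")
  expect_equal(v$input_k, 100L)
  expect_equal(n_layers(v), 12L)
  kinds <- vapply(v$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "lstm"), 2)
  expect_equal(sum(kinds == "conv-1d"), 2)

  g <- model_preset("GAXJPR")
  expect_equal(g$input_k, 1000L)
  expect_equal(n_layers(g), 4L)

  t3 <- model_preset("3TXKFS")
  expect_equal(t3$n_classes, 3L)
  expect_equal(t3$input_k, 1000L)
  expect_equal(n_layers(t3), 3L)

  expect_error(model_preset("NOPE"), "XPILJZ")
})

test_that("training reaches >= 0.99 validation accuracy on separable data", {
  pool <- toy_separable_pool(1200, seed = 1)
  tr <- structure(pool, class = "labeled_pool")
  tr$features <- pool$features[1:1000, ]; tr$labels <- pool$labels[1:1000]
  va <- pool; va$features <- pool$features[1001:1200, ]
  va$labels <- pool$labels[1001:1200]; va$split <- "val"
  m <- train_model(model_preset("XPILJZ"), tr, va, epochs = 10, seed = 2)
  expect_gte(m$training_meta$val_accuracy, 0.99)
  expect_s3_class(m, "trained_model")
  expect_true(all(c("epoch", "train_loss", "train_acc", "val_acc") %in%
                    names(m$history)))
})

test_that("training is deterministic for a fixed seed", {
  tr <- toy_separable_pool(400, seed = 3)
  va <- toy_separable_pool(100, seed = 4, split = "val")
  m1 <- train_model(model_preset("XPILJZ"), tr, va, epochs = 3, seed = 7)
  m2 <- train_model(model_preset("XPILJZ"), tr, va, epochs = 3, seed = 7)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$nodes, m2$nodes)
})

test_that("width/arity mismatches are rejected as shape errors", {
  tr <- toy_separable_pool(100, k = 50, seed = 1)
  va <- toy_separable_pool(50, k = 50, seed = 2)
  expect_error(train_model(model_preset("XPILJZ"), tr, va), "input_k")
})

test_that("score rows sum to 1 and survive row duplication", {
  tr <- toy_separable_pool(400, seed = 5)
  va <- toy_separable_pool(100, seed = 6, split = "val")
  m <- train_model(model_preset("XPILJZ"), tr, va, epochs = 5, seed = 1)
  p <- predict(m, va)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  dup <- rbind(va$features[1, , drop = FALSE], va$features[1, , drop = FALSE])
  pd <- predict(m, dup)
  expect_identical(pd[1, ], pd[2, ])
})

test_that("evaluation metrics reproduce the hand-computed confusion", {
  # confusion [[40,10],[5,45]] -> acc .85, clustered prec 45/55, rec .9
  truth <- c(rep(0L, 50), rep(1L, 50))
  pred <- c(rep(0L, 40), rep(1L, 10), rep(0L, 5), rep(1L, 45))
  mt <- smlmclust:::metrics_from_labels(truth, pred, 2L)
  expect_equal(unname(mt$confusion), matrix(c(40, 5, 10, 45), 2))
  expect_equal(mt$accuracy, 0.85)
  expect_equal(mt$per_class$precision[2], 45 / 55)
  expect_equal(mt$per_class$recall[2], 0.90)
  expect_equal(mt$per_class$f1[2], 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9))
  expect_equal(mt$per_class$f1[2], 0.8571, tolerance = 1e-4)
  # macro averages are the per-class means
  expect_equal(mt$f1, mean(mt$per_class$f1))
})

test_that("perfect predictions score 1 and permuted labels complement", {
  truth <- rep(c(0L, 1L), 30)
  perfect <- smlmclust:::metrics_from_labels(truth, truth, 2L)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))
  set.seed(8)
  pred <- rbinom(60, 1, 0.5)
  a <- smlmclust:::metrics_from_labels(truth, pred, 2L)$accuracy
  b <- smlmclust:::metrics_from_labels(truth, 1L - pred, 2L)$accuracy
  expect_equal(a + b, 1)
})

test_that("cross-validation is stratified, exhaustive and accurate on toys", {
  pool <- toy_separable_pool(1000, seed = 1)
  spec <- model_preset("XPILJZ")
  cv <- cross_validate(spec, pool, n_folds = 10, seed = 3,
                       epochs = 30, batch_size = 64)
  expect_gte(cv$mean, 0.99)
  expect_lte(cv$sd, 0.01)
  # folds partition the pool and are stratified
  expect_length(cv$folds, 1000)
  expect_setequal(unique(cv$folds), 1:10)
  per_fold <- table(cv$folds, pool$labels)
  expect_true(all(abs(per_fold[, "1"] - mean(per_fold[, "1"])) <= 1))
  expect_error(cross_validate(spec, pool, n_folds = 1), "n_folds")
})

test_that("classification hard labels follow the documented tie rule", {
  expect_equal(smlmclust:::hard_labels(matrix(c(0.5, 0.5), 1), 0.5), 1L)
  expect_equal(smlmclust:::hard_labels(matrix(c(0.1, 0.9, 0.9, 0.1),
                                              2, byrow = TRUE), 0.5),
               c(1L, 0L))
})

test_that("lowering the threshold never decreases clustered count", {
  tr <- toy_separable_pool(400, seed = 9)
  va <- toy_separable_pool(100, seed = 10, split = "val")
  m <- train_model(model_preset("XPILJZ"), tr, va, epochs = 5, seed = 1)
  fm <- structure(list(values = toy_separable_pool(200, seed = 11)$features,
                       idx = NULL, k = 100L, dims = 2L,
                       representation = "distance"),
                  class = "feature_matrix")
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(th)
    sum(classify_points(m, fm, threshold = th)$label), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classify_points enforces the input window", {
  tr <- toy_separable_pool(300, seed = 1)
  va <- toy_separable_pool(100, seed = 2, split = "val")
  m <- train_model(model_preset("XPILJZ"), tr, va, epochs = 2, seed = 1)
  fm <- structure(list(values = matrix(runif(50 * 60), 50), idx = NULL,
                       k = 60L, dims = 2L, representation = "distance"),
                  class = "feature_matrix")
  expect_error(classify_points(m, fm), "input")
})

test_that("model save/load round-trips weights and metadata exactly", {
  tr <- toy_separable_pool(300, seed = 1)
  va <- toy_separable_pool(100, seed = 2, split = "val")
  m <- train_model(model_preset("XPILJZ"), tr, va, epochs = 3, seed = 4)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "spec.json")))
  back <- load_model(dir)
  expect_equal(back$spec$name, "XPILJZ")
  p1 <- predict(m, va)
  p2 <- predict(back, va)
  expect_identical(p1, p2)
})

test_that("a 3-class model trains on three separable populations", {
  set.seed(12)
  n <- 900; k <- 60
  base <- t(apply(matrix(runif(n * k), n), 1, sort))
  cl <- rep(0:2, each = n / 3)
  X <- base * c(1, 0.3, 0.05)[cl + 1]
  ord <- sample(n)
  mkpool <- function(ix, split) structure(
    list(features = X[ix, ], labels = cl[ix], split = split, k = k,
         representation = "distance"), class = "labeled_pool")
  m <- train_model(model_spec(k, 3, list(layer_dense(32)), name = "toy3"),
                   mkpool(ord[1:720], "train"), mkpool(ord[721:900], "val"),
                   # small batches: 45 Adam steps/epoch so the model moves
                   # off its flat start before early stopping can fire
                   epochs = 40, batch_size = 16, seed = 5)
  expect_gte(m$training_meta$val_accuracy, 0.95)
  sc <- predict(m, X[ord[721:900], ])
  expect_equal(rowSums(sc), rep(1, 180), tolerance = 1e-6)
})
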