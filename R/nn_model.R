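#' Specify a sequential classification network
#'
#' Assembles a model specification from an input width, a class count
#' and an ordered list of processing layers (see [layers]).  An input
#' layer is prepended and a softmax output layer emitting `n_classes`
#' scores is appended, so `n_layers()` counts
#' `input + processing + output`.
#'
#' @param input_k Number of nearest-neighbour values consumed (the input
#'   window).
#' @param n_classes 2 for clustered/not-clustered, 3 when a separate
#'   fiber class is modelled.
#' @param layers List of layer descriptors from [layer_dense()] and
#'   friends.
#' @param name Optional identifier.
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec(100, 2, list(layer_dense(128), layer_dense(64)))
#' n_layers(spec)
#' @export
model_spec <- function(input_k, n_classes = 2L, layers = list(),
                       name = "custom") {
  input_k <- as.integer(input_k)
  n_classes <- as.integer(n_classes)
  stopifnot(input_k >= 1, n_classes %in% c(2L, 3L) || n_classes >= 2L)
  full <- c(list(list(kind = "input", k = input_k)),
            layers,
            list(list(kind = "output-softmax", n_classes = n_classes)))
  structure(list(name = name, input_k = input_k, n_classes = n_classes,
                 layers = full),
            class = "model_spec")
}

#' @rdname model_spec
#' @param spec A `model_spec`.
#' @export
n_layers <- function(spec) length(spec$layers)

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': input %d, %d classes, %d layers\n",
              x$name, x$input_k, x$n_classes, n_layers(x)))
  for (ly in x$layers) {
    cat("  -", ly$kind)
    extras <- ly[setdiff(names(ly), "kind")]
    if (length(extras))
      cat(" (", paste(names(extras), unlist(extras), sep = "=",
                      collapse = ", "), ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Published model presets
#'
#' Returns the architecture of one of the named example models:
#' \describe{
#'   \item{XPILJZ}{4 layers: input for 100 near-neighbour values, two
#'     fully connected layers, binary softmax output.}
#'   \item{07VEJJ}{12 layers: input 100, two conv-1d/max-pool/dropout
#'     stages, two stacked LSTM layers, dropout, a dense layer and the
#'     binary output.}
#'   \item{87B144}{identical to 07VEJJ but with a 1000-neighbour input
#'     window (for larger, denser clusters).}
#'   \item{GAXJPR}{XPILJZ's four-layer arrangement with a 1000-neighbour
#'     window, intended for 3D nearest-neighbour distances.}
#'   \item{3TXKFS}{3 layers: input 1000, one fully connected layer, and
#'     a 3-class output (not clustered / clustered / clustered-fiber).}
#' }
#' Only the layer topology of these models is published; widths, kernel
#' sizes and dropout rates here are this package's defaults and are
#' fully configurable through [model_spec()].
#'
#' @param name One of `"XPILJZ"`, `"07VEJJ"`, `"87B144"`, `"GAXJPR"`,
#'   `"3TXKFS"`.
#' @return A `model_spec`.
#' @examples
#' model_preset("XPILJZ")
#' @export
model_preset <- function(name) {
  lstm_stack <- function() list(
    layer_conv1d(32, 5), layer_maxpool(2), layer_dropout(0.25),
    layer_conv1d(64, 5), layer_maxpool(2), layer_dropout(0.25),
    layer_lstm(64, return_sequences = TRUE), layer_lstm(32),
    layer_dropout(0.25), layer_dense(32))
  switch(name,
    "XPILJZ" = model_spec(100, 2, list(layer_dense(128), layer_dense(64)),
                          name = "XPILJZ"),
    "07VEJJ" = model_spec(100, 2, lstm_stack(), name = "07VEJJ"),
    "87B144" = model_spec(1000, 2, lstm_stack(), name = "87B144"),
    "GAXJPR" = model_spec(1000, 2, list(layer_dense(128), layer_dense(64)),
                          name = "GAXJPR"),
    "3TXKFS" = model_spec(1000, 3, list(layer_dense(128)), name = "3TXKFS"),
    abort_param(
      "unknown preset '%s'; valid names: XPILJZ, 07VEJJ, 87B144, GAXJPR, 3TXKFS",
      name))
}

check_pool_shape <- function(spec, pool, what) {
  if (ncol(pool$features) != spec$input_k)
    abort_param("%s pool width %d does not match model input_k %d",
                what, ncol(pool$features), spec$input_k)
  bad <- pool$labels < 0 | pool$labels >= spec$n_classes
  if (any(bad))
    abort_param("%s pool labels outside 0..%d", what, spec$n_classes - 1L)
}

#' Train a classification network
#'
#' Mini-batch training with the Adam optimizer and softmax
#' cross-entropy loss.  Training stops early when validation accuracy
#' has not improved for `patience` epochs; the parameters from the best
#' validation epoch are kept.  Deterministic for a fixed seed under
#' single-threaded numerics.
#'
#' @param spec A `model_spec`.
#' @param train_pool,val_pool `labeled_pool`s whose feature width
#'   matches `spec$input_k`.
#' @param epochs Maximum epochs (default 50).
#' @param batch_size Mini-batch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param seed Integer seed for weight initialization, batch order and
#'   dropout.
#' @param verbose Print per-epoch progress.
#' @return An object of class `trained_model` with the compiled network,
#'   per-epoch `history` (train loss/accuracy, validation accuracy) and
#'   `training_meta`.
#' @export
train_model <- function(spec, train_pool, val_pool, epochs = 50L,
                        batch_size = 256L, lr = 1e-3, patience = 5L,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  check_pool_shape(spec, train_pool, "training")
  check_pool_shape(spec, val_pool, "validation")
  X <- train_pool$features
  y <- as.integer(train_pool$labels)
  n <- nrow(X)

  withr_seed(seed, {
    nodes <- compile_network(spec)
    opt <- adam_init(nodes, lr)
    best <- list(acc = -Inf, nodes = nodes, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_acc = numeric(), val_acc = numeric())
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        ix <- ord[b0:min(b0 + batch_size - 1L, n)]
        xb <- X[ix, , drop = FALSE]
        fw <- net_forward(nodes, xb, training = TRUE)
        lo <- softmax_xent(fw$out, y[ix])
        if (!is.finite(lo$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
               call. = FALSE)
        grads <- net_backward(nodes, fw$caches, lo$dlogits)
        nodes <- adam_step(nodes, grads, opt)
        tot_loss <- tot_loss + lo$loss * length(ix)
        tot_correct <- tot_correct +
          sum(max.col(lo$p, ties.method = "last") - 1L == y[ix])
      }
      val_acc <- pool_accuracy(nodes, val_pool, batch_size = 8192L)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = tot_loss / n,
        train_acc = tot_correct / n, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train acc %.4f  val acc %.4f",
                        ep, tot_loss / n, tot_correct / n, val_acc))
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, nodes = nodes, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(
      spec = spec, nodes = best$nodes, history = hist,
      training_meta = list(
        seed = seed, epochs_run = nrow(hist), best_epoch = best$epoch,
        batch_size = batch_size, lr = lr, patience = patience,
        representation = train_pool$representation,
        n_train = n, n_val = nrow(val_pool$features),
        val_accuracy = best$acc)
    ), class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "trained_model '%s': %d epochs (best %d), validation accuracy %.4f\n",
    x$spec$name, x$training_meta$epochs_run, x$training_meta$best_epoch,
    x$training_meta$val_accuracy))
  invisible(x)
}

adam_init <- function(nodes, lr) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$b1 <- 0.9; e$b2 <- 0.999; e$eps <- 1e-8; e$t <- 0L
  e$m <- lapply(nodes, function(nd)
    if (is.null(nd$params)) NULL else lapply(nd$params, function(p) p * 0))
  e$v <- e$m
  e
}

adam_step <- function(nodes, grads, opt) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t
  c2 <- 1 - opt$b2^opt$t
  for (i in seq_along(nodes)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (pn in names(g)) {
      opt$m[[i]][[pn]] <- opt$b1 * opt$m[[i]][[pn]] + (1 - opt$b1) * g[[pn]]
      opt$v[[i]][[pn]] <- opt$b2 * opt$v[[i]][[pn]] + (1 - opt$b2) * g[[pn]]^2
      nodes[[i]]$params[[pn]] <- nodes[[i]]$params[[pn]] -
        opt$lr * (opt$m[[i]][[pn]] / c1) /
          (sqrt(opt$v[[i]][[pn]] / c2) + opt$eps)
    }
  }
  nodes
}

# class scores for a feature matrix, batched to bound memory
net_scores <- function(nodes, X, batch_size = 8192L) {
  n <- nrow(X)
  out <- NULL
  for (b0 in seq(1L, n, by = batch_size)) {
    ix <- b0:min(b0 + batch_size - 1L, n)
    p <- softmax(net_forward(nodes, X[ix, , drop = FALSE])$out)
    out <- if (is.null(out)) p else rbind(out, p)
  }
  out
}

pool_accuracy <- function(nodes, pool, batch_size = 8192L) {
  p <- net_scores(nodes, pool$features, batch_size)
  mean(max.col(p, ties.method = "last") - 1L == pool$labels)
}

#' Predict class scores
#'
#' @param object A `trained_model`.
#' @param newdata Feature matrix (rows of `input_k` values) or a
#'   `labeled_pool` or `feature_matrix`.
#' @param ... Unused.
#' @return Matrix of per-point class scores (rows sum to 1).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_pool")) newdata$features
       else if (inherits(newdata, "feature_matrix")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != object$spec$input_k)
    abort_param("feature width %d does not match model input_k %d",
                ncol(X), object$spec$input_k)
  net_scores(object$nodes, X)
}

#' Evaluate a trained model on a labeled pool
#'
#' Computes the confusion matrix, overall accuracy and macro-averaged
#' precision, recall and F1.  For binary models the hard label uses the
#' clustered-class score with a 0.5 cutoff (ties to "clustered"), which
#' coincides with the argmax rule except exactly at the tie.
#'
#' @param model A `trained_model`.
#' @param pool A `labeled_pool`.
#' @return A list of class `model_metrics`: `accuracy`, `precision`,
#'   `recall`, `f1` (macro averages), `per_class` data.frame, and
#'   `confusion` (true x predicted counts).
#' @export
evaluate_model <- function(model, pool) {
  check_pool_shape(model$spec, pool, "test")
  if (nrow(pool$features) == 0) abort_param("empty pool")
  p <- predict(model, pool)
  pred <- hard_labels(p, threshold = 0.5)
  metrics_from_labels(pool$labels, pred, model$spec$n_classes)
}

hard_labels <- function(scores, threshold = 0.5) {
  if (ncol(scores) == 2L) {
    as.integer(scores[, 2] >= threshold)
  } else {
    max.col(scores, ties.method = "first") - 1L
  }
}

metrics_from_labels <- function(truth, pred, n_classes) {
  lv <- 0:(n_classes - 1L)
  confusion <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(true = lv, predicted = lv)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    accuracy = sum(tp) / sum(confusion),
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    per_class = data.frame(class = lv, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1)),
    confusion = confusion
  ), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the pool into stratified folds, trains one model per fold on
#' the remaining data (carving a tenth of it off as the early-stopping
#' validation set) and evaluates on the held-out fold.
#'
#' @param spec A `model_spec`.
#' @param pool A `labeled_pool`.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed controlling fold assignment and training.
#' @param ... Passed to [train_model()] (e.g. `epochs`).
#' @return List with `mean`, `sd` and the vector `fold_accuracy`.
#' @export
cross_validate <- function(spec, pool, n_folds = 10L, seed = 1L, ...) {
  n <- nrow(pool$features)
  if (n_folds < 2) abort_param("n_folds must be >= 2")
  if (n < n_folds) abort_param("pool of %d rows is too small for %d folds",
                               n, n_folds)
  folds <- withr_seed(seed, {
    f <- integer(n)
    for (cl in unique(pool$labels)) {
      ix <- sample(which(pool$labels == cl))
      f[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
    f
  })
  accs <- vapply(seq_len(n_folds), function(fd) {
    tr_ix <- which(folds != fd)
    te_ix <- which(folds == fd)
    n_val <- max(1L, length(tr_ix) %/% 10L)
    val_ix <- withr_seed(seed + fd, sample(tr_ix, n_val))
    fit_ix <- setdiff(tr_ix, val_ix)
    mk <- function(ix, split) structure(
      list(features = pool$features[ix, , drop = FALSE],
           labels = pool$labels[ix], split = split, k = pool$k,
           representation = pool$representation), class = "labeled_pool")
    m <- train_model(spec, mk(fit_ix, "train"), mk(val_ix, "val"),
                     seed = seed + fd, ...)
    pool_accuracy(m$nodes, mk(te_ix, "test"))
  }, numeric(1))
  list(mean = mean(accs), sd = sd(accs), fold_accuracy = accs,
       folds = folds)
}

#' Classify every point of a field
#'
#' Applies a trained model to a feature matrix and returns per-point
#' class scores and hard labels, preserving input order.  If the model
#' was trained on a transformed representation and `fm` still holds raw
#' distances, the transformation is applied automatically.
#'
#' @param model A `trained_model`.
#' @param fm A `feature_matrix` with `k == model$spec$input_k`.
#' @param threshold Binary decision cutoff on the clustered-class score
#'   (default 0.5; a score exactly at the threshold is labelled
#'   clustered).
#' @return An object of class `point_labels`: list with `scores` matrix
#'   and integer `label` vector.
#' @export
classify_points <- function(model, fm, threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (threshold <= 0 || threshold >= 1)
    abort_param("threshold must lie strictly between 0 and 1")
  if (fm$k != model$spec$input_k)
    abort_param("feature k = %d does not match model input_k = %d",
                fm$k, model$spec$input_k)
  want <- model$training_meta$representation %||% fm$representation
  if (fm$representation == "distance" && want != "distance")
    fm <- apply_representation(fm, want)
  else if (fm$representation != want)
    abort_param("features are '%s' but the model was trained on '%s'",
                fm$representation, want)
  scores <- predict(model, fm)
  structure(list(scores = scores,
                 label = hard_labels(scores, threshold),
                 threshold = threshold),
            class = "point_labels")
}

#' @export
print.point_labels <- function(x, ...) {
  tb <- table(x$label)
  cat(sprintf("point_labels: %d points (%s)\n", length(x$label),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Persist and restore trained models
#'
#' A model directory holds `spec.json` (architecture, featurization
#' settings, seed and training description) and `weights.bin` (raw
#' little-endian doubles with a shape manifest), so a stored model can
#' refuse incompatible features on load.
#'
#' @param model A `trained_model`.
#' @param dir Directory to create/use.
#' @return `dir` (save) or the restored `trained_model` (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pn <- which(!vapply(model$nodes, function(nd) is.null(nd$params),
                      logical(1)))
  shapes <- lapply(model$nodes[pn], function(nd)
    lapply(nd$params, function(p) if (is.matrix(p)) dim(p) else length(p)))
  meta <- list(spec = model$spec[c("name", "input_k", "n_classes")],
               layers = model$spec$layers,
               training_meta = model$training_meta,
               shapes = shapes,
               history = model$history)
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (nd in model$nodes)
    if (!is.null(nd$params))
      for (p in nd$params) writeBin(as.vector(p), con, size = 8,
                                    endian = "little")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "spec.json"),
                             simplifyVector = FALSE)
  core <- meta$layers[!vapply(meta$layers, function(l)
    l$kind %in% c("input", "output-softmax"), logical(1))]
  spec <- model_spec(meta$spec$input_k, meta$spec$n_classes, core,
                     name = meta$spec$name)
  nodes <- withr_seed(0L, compile_network(spec))
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  si <- 0L
  for (i in seq_along(nodes)) {
    if (is.null(nodes[[i]]$params)) next
    si <- si + 1L
    shp <- meta$shapes[[si]]
    for (pn in names(nodes[[i]]$params)) {
      d <- unlist(shp[[pn]])
      vals <- readBin(con, "double", prod(d), size = 8, endian = "little")
      nodes[[i]]$params[[pn]] <- if (length(d) == 2) matrix(vals, d[1], d[2])
                                 else vals
    }
  }
  hist <- jsonlite::fromJSON(file.path(dir, "spec.json"))$history
  structure(list(spec = spec, nodes = nodes,
                 history = as.data.frame(hist),
                 training_meta = meta$training_meta),
            class = "trained_model")
}
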