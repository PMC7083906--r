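#' Per-point nearest-neighbour distance sequences
#'
#' Computes, for every localization, the sorted Euclidean distances to
#' its `k` nearest other points (2D or 3D according to the table).  This
#' monotonic distance sequence is the input representation consumed by
#' the classification networks: the first entries of a clustered point
#' are compressed relative to a CSR point at the same overall density.
#'
#' The search is exact (brute force with partial selection); distance
#' ties are broken by point id, which can affect neighbour identity but
#' never the distance values themselves.
#'
#' @param table A localization data.frame with columns `x`, `y` and
#'   optionally `z` (nm), e.g. from [simulate_field()] or
#'   [read_localizations()].
#' @param k Number of neighbours (the model input window).  Requires
#'   `nrow(table) > k`.
#' @return An object of class `feature_matrix`: list with `values`
#'   (n x k matrix of distances, nm), `idx` (n x k neighbour indices,
#'   used later by segmentation), `k`, `dims` and
#'   `representation = "distance"`.
#' @examples
#' tab <- data.frame(x = c(0, 3, 7), y = 0)
#' knn_distances(tab, k = 2)$values
#' @export
knn_distances <- function(table, k) {
  k <- as.integer(k)
  n <- nrow(table)
  if (n <= k)
    abort_param("need n > k for k-NN features: n = %d points, k = %d", n, k)
  dims <- if (!is.null(table$z)) 3L else 2L
  coords <- if (dims == 3L) cbind(table$x, table$y, table$z) else
    cbind(table$x, table$y)
  if (!all(is.finite(coords)))
    abort_param("coordinates must all be finite")
  res <- .knn_brute_cpp(coords, k)
  structure(list(values = res$dist, idx = res$idx, k = k, dims = dims,
                 representation = "distance"),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d points x %d neighbours (%s, %dD)\n",
              nrow(x$values), x$k, x$representation, x$dims))
  invisible(x)
}

#' Consecutive-distance differences
#'
#' Transforms each distance row `d1..dk` into the difference sequence
#' `d1, d2 - d1, ..., dk - d(k-1)`; the cumulative sum restores the
#' original row exactly.
#'
#' @param fm A `feature_matrix` with `representation = "distance"`.
#' @return The transformed `feature_matrix`
#'   (`representation = "difference"`).
#' @export
to_differences <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$representation != "distance")
    abort_param("to_differences() needs representation 'distance', got '%s'",
                fm$representation)
  v <- fm$values
  out <- cbind(v[, 1, drop = FALSE],
               v[, -1, drop = FALSE] - v[, -ncol(v), drop = FALSE])
  fm$values <- out
  fm$representation <- "difference"
  fm
}

#' Per-row normalized distances
#'
#' Divides each distance row by its own k-th (largest) entry, so every
#' row ends at exactly 1 and the representation becomes invariant to the
#' overall density scale.  This is the default input fed to the models.
#'
#' @param fm A `feature_matrix` with `representation = "distance"`.
#' @return The transformed `feature_matrix`
#'   (`representation = "normalized-distance"`).
#' @export
to_normalized <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$representation != "distance")
    abort_param("to_normalized() needs representation 'distance', got '%s'",
                fm$representation)
  last <- fm$values[, ncol(fm$values)]
  if (any(last <= 0))
    abort_param("degenerate rows: %d point(s) have all %d neighbours coincident",
                sum(last <= 0), fm$k)
  fm$values <- fm$values / last
  fm$representation <- "normalized-distance"
  fm
}

apply_representation <- function(fm, representation) {
  switch(representation,
         "distance" = fm,
         "difference" = to_differences(fm),
         "normalized-distance" = ,
         "normalized" = to_normalized(fm),
         abort_param("unknown representation '%s'", representation))
}

#' Assemble balanced train/validation/test pools
#'
#' Pools feature rows and ground-truth labels from any number of
#' simulated fields, then draws three mutually disjoint random subsets.
#' With `balance = TRUE` each split contains an even mix of the classes
#' (counts per class differ by at most 1 within a split).
#'
#' @param datasets List of `list(features = <feature_matrix>,
#'   truth = <data.frame with $label>)` pairs, or `sim_field` objects
#'   augmented with a `features` element.
#' @param n_train,n_val,n_test Requested split sizes (rows).
#' @param balance Balance classes within each split (default `TRUE`).
#' @param seed Integer seed; sampling is deterministic per seed.
#' @return List with elements `train`, `val`, `test`, each a
#'   `labeled_pool`: list with `features` (matrix), `labels` (integer
#'   vector), `split`, `k`, `representation`.
#' @export
build_training_pool <- function(datasets, n_train, n_val, n_test,
                                balance = TRUE, seed = 1L) {
  feats <- lapply(datasets, function(d) d$features$values)
  labs <- lapply(datasets, function(d) as.integer(d$truth$label))
  k <- unique(vapply(datasets, function(d) d$features$k, integer(1)))
  rep_ <- unique(vapply(datasets, function(d) d$features$representation,
                        character(1)))
  if (length(k) != 1 || length(rep_) != 1)
    abort_param("all datasets must share one k and one representation")
  X <- do.call(rbind, feats)
  y <- unlist(labs, use.names = FALSE)
  classes <- sort(unique(y))

  withr_seed(seed, {
    sizes <- c(train = n_train, val = n_val, test = n_test)
    if (balance) {
      n_cl <- length(classes)
      per_class <- lapply(sizes, function(s) {
        base <- s %/% n_cl
        extra <- s - base * n_cl
        cnt <- rep(base, n_cl)
        if (extra > 0) cnt[seq_len(extra)] <- cnt[seq_len(extra)] + 1L
        cnt
      })
      need <- Reduce(`+`, per_class)
      avail <- vapply(classes, function(cl) sum(y == cl), numeric(1))
      short <- need > avail
      if (any(short))
        abort_param(paste0(
          "insufficient rows for class %s: need %d, have %d"),
          paste(classes[short], collapse = ","),
          max(need[short]), min(avail[short]))
      pick <- lapply(seq_along(classes), function(ci) {
        pool <- sample(which(y == classes[ci]))
        splits <- vector("list", 3)
        off <- 0L
        for (s in 1:3) {
          splits[[s]] <- pool[off + seq_len(per_class[[s]][ci])]
          off <- off + per_class[[s]][ci]
        }
        splits
      })
      sel <- lapply(1:3, function(s)
        sample(unlist(lapply(pick, `[[`, s))))  # shuffle class order
    } else {
      total <- sum(sizes)
      if (total > length(y))
        abort_param("requested %d rows but only %d available", total, length(y))
      pool <- sample.int(length(y), total)
      sel <- list(pool[seq_len(sizes[1])],
                  pool[sizes[1] + seq_len(sizes[2])],
                  pool[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
    names(sel) <- c("train", "val", "test")
    out <- lapply(names(sel), function(s) {
      structure(list(features = X[sel[[s]], , drop = FALSE],
                     labels = y[sel[[s]]],
                     split = s, k = k, representation = rep_),
                class = "labeled_pool")
    })
    names(out) <- names(sel)
    out
  })
}

#' @export
print.labeled_pool <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("labeled_pool (%s): %d rows x %d features [%s]; classes: %s\n",
              x$split, nrow(x$features), ncol(x$features), x$representation,
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Write/read a feature container
#'
#' Features are the most expensive stage of the pipeline, so they are
#' persisted in a simple container (JSON header line followed by
#' little-endian doubles, row-major) and can be re-used across models.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path (conventionally `.knn`).
#' @param source Optional path of the localization file the features
#'   came from; its md5 is recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path, source = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  hdr <- list(format = "smlmclust-knn", version = 1L,
              n = nrow(fm$values), k = fm$k, dims = fm$dims,
              representation = fm$representation,
              source = source,
              source_md5 = if (!is.null(source))
                unname(tools::md5sum(source)) else NULL)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, null = "null"), con)
  writeBin(as.vector(t(fm$values)), con, size = 8, endian = "little")
  writeBin(as.vector(t(fm$idx)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1))
  if (!identical(hdr$format, "smlmclust-knn"))
    abort_param("'%s' is not a feature container", path)
  n <- hdr$n; k <- hdr$k
  vals <- matrix(readBin(con, "double", n * k, size = 8, endian = "little"),
                 nrow = n, byrow = TRUE)
  idx <- matrix(readBin(con, "integer", n * k, size = 4, endian = "little"),
                nrow = n, byrow = TRUE)
  structure(list(values = vals, idx = idx, k = as.integer(k),
                 dims = as.integer(hdr$dims),
                 representation = hdr$representation),
            class = "feature_matrix")
}
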