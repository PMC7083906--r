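#' Simulate fields and assemble training pools in one step
#'
#' Drives the simulation and featurization stages over a list of
#' scenarios: one or more fields per scenario are simulated inside the
#' given cell, featurized at `k` neighbours, transformed to the
#' requested representation, optionally thinned per field, and pooled
#' into balanced train/validation/test splits.
#'
#' @param scenarios List of `cluster_scenario` (typically
#'   [viable_scenarios()] of a grid, possibly subsampled).
#' @param cell A `cell_shape` shared by all fields.
#' @param k Input window (neighbour count).
#' @param representation `"normalized-distance"` (default),
#'   `"distance"` or `"difference"`.
#' @param n_train,n_val,n_test Pool sizes.
#' @param seed Master seed; per-field seeds are derived from it.
#' @param fields_per_scenario Fields simulated per scenario.
#' @param max_rows_per_field Random thinning cap applied per field
#'   before pooling (keeps memory bounded at large `k`).
#' @param check_viability Refuse non-viable scenarios (default `TRUE`).
#' @return List with `train`, `val`, `test` pools (see
#'   [build_training_pool()]) and `n_fields`.
#' @export
simulate_training_pools <- function(scenarios, cell = generate_cell_shape(),
                                    k = 100L,
                                    representation = "normalized-distance",
                                    n_train = 50000L, n_val = 10000L,
                                    n_test = 10000L, seed = 1L,
                                    fields_per_scenario = 1L,
                                    max_rows_per_field = Inf,
                                    check_viability = TRUE) {
  n_fields <- length(scenarios) * fields_per_scenario
  field_seeds <- withr_seed(seed, sample.int(.Machine$integer.max, n_fields))
  datasets <- vector("list", n_fields)
  fi <- 0L
  for (sc in scenarios) {
    for (r in seq_len(fields_per_scenario)) {
      fi <- fi + 1L
      fld <- simulate_field(sc, cell, seed = field_seeds[fi],
                            check_viability = check_viability)
      fm <- apply_representation(knn_distances(fld$table, k), representation)
      lab <- fld$truth$label
      if (is.finite(max_rows_per_field) &&
          nrow(fm$values) > max_rows_per_field) {
        keep <- withr_seed(field_seeds[fi] %% 100000L + 7L,
                           sample.int(nrow(fm$values), max_rows_per_field))
        fm$values <- fm$values[keep, , drop = FALSE]
        lab <- lab[keep]
      }
      datasets[[fi]] <- list(
        features = list(values = fm$values, k = fm$k,
                        representation = fm$representation),
        truth = data.frame(label = pmin(lab, 1L)))
    }
  }
  pools <- build_training_pool(datasets, n_train, n_val, n_test,
                               balance = TRUE, seed = seed)
  pools$n_fields <- n_fields
  pools
}

#' Deterministically subsample a scenario list
#'
#' @param scenarios List of `cluster_scenario`.
#' @param n Number to keep (all if `n >= length`).
#' @param seed Integer seed.
#' @return Subsampled list.
#' @export
sample_scenarios <- function(scenarios, n, seed = 1L) {
  if (n >= length(scenarios)) return(scenarios)
  scenarios[sort(withr_seed(seed, sample.int(length(scenarios), n)))]
}

peek_features_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  jsonlite::fromJSON(readLines(con, n = 1))
}

#' Run the staged pipeline from a configuration
#'
#' Executes the requested subset of the discrete processing stages
#' `simulate -> featurize -> (train | classify) -> segment -> report`,
#' each stage writing files that the next stage (or an external tool)
#' can consume independently.  Stage compatibility (model input window
#' vs feature k) is checked from the file headers before any heavy
#' computation.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list,
#'   with an `out_dir`, an optional `seed`, and one entry per requested
#'   stage:
#' \preformatted{
#' out_dir: results
#' seed: 1
#' simulate:
#'   cell: {seed: 1, mean_diameter_um: 10, irregularity: 0.25}
#'   scenarios: {density: [100], pct: [50], ppc: [10], radius: [30, 50]}
#'   cluster_model: uniform-disc
#'   check_viability: true
#' featurize: {k: 100, representation: normalized-distance}
#' train: {preset: XPILJZ, n_train: 50000, n_val: 10000, n_test: 10000}
#' classify: {model: results/model}
#' segment: {min_cluster_size: 3, disc_factor: 1.0, erosion_factor: 0.5}
#' report: {}
#' }
#' @return Invisibly, a list of the per-stage outputs.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  res <- list()
  log_stage <- function(...) message(sprintf(...))

  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    cell <- do.call(generate_cell_shape, as.list(s$cell %||% list()))
    scen <- enumerate_scenarios(lapply(s$scenarios, unlist),
                                cluster_model = s$cluster_model %||%
                                  "uniform-disc",
                                axial_range_nm = s$axial_range_nm %||% 0)
    if (isTRUE(s$check_viability %||% TRUE))
      scen <- viable_scenarios(scen, cell)
    fdir <- file.path(out_dir, "fields")
    dir.create(fdir, showWarnings = FALSE)
    n_fields <- as.integer(s$n_fields %||% 1L)
    paths <- character(0)
    fi <- 0L
    for (sc in scen) for (r in seq_len(n_fields)) {
      fi <- fi + 1L
      fld <- simulate_field(sc, cell, seed = seed + fi,
                            check_viability = FALSE)
      p <- file.path(fdir, sprintf("field_%03d.csv", fi))
      write_field(fld, p)
      paths <- c(paths, p)
    }
    log_stage("simulate: wrote %d field(s) to %s", length(paths), fdir)
    res$simulate <- paths
  }

  if (!is.null(cfg$featurize)) {
    f <- cfg$featurize
    k <- as.integer(f$k %||% 100L)
    rep_ <- f$representation %||% "normalized-distance"
    in_paths <- if (!is.null(f$batch)) {
      list.files(f$batch, pattern = "\\.csv$", full.names = TRUE)
    } else res$simulate %||%
      list.files(file.path(out_dir, "fields"), pattern = "\\.csv$",
                 full.names = TRUE)
    outs <- character(0)
    for (p in in_paths) {
      tab <- read_localizations(p)
      fm <- apply_representation(knn_distances(tab, k), rep_)
      op <- sub("\\.csv$", ".knn", p)
      write_features(fm, op, source = p)
      outs <- c(outs, op)
    }
    log_stage("featurize: %d file(s) at k = %d (%s)", length(outs), k, rep_)
    res$featurize <- outs
  }

  if (!is.null(cfg$train)) {
    t <- cfg$train
    spec <- if (!is.null(t$preset)) model_preset(t$preset)
            else do.call(model_spec, t$spec)
    fm_paths <- res$featurize %||%
      list.files(file.path(out_dir, "fields"), pattern = "\\.knn$",
                 full.names = TRUE)
    datasets <- lapply(fm_paths, function(p) {
      fm <- read_features(p)
      tab <- read_localizations(sub("\\.knn$", ".csv", p))
      list(features = fm, truth = data.frame(label = pmin(tab$label, 1L)))
    })
    pools <- build_training_pool(datasets, t$n_train %||% 50000L,
                                 t$n_val %||% 10000L,
                                 t$n_test %||% 10000L, seed = seed)
    model <- train_model(spec, pools$train, pools$val,
                         epochs = t$epochs %||% 50L, seed = seed)
    metrics <- evaluate_model(model, pools$test)
    mdir <- file.path(out_dir, "model")
    save_model(model, mdir)
    jsonlite::write_json(
      list(accuracy = metrics$accuracy, precision = metrics$precision,
           recall = metrics$recall, f1 = metrics$f1,
           confusion = metrics$confusion, history = model$history),
      file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("train: %s test accuracy %.4f", spec$name, metrics$accuracy)
    res$train <- mdir
  }

  if (!is.null(cfg$classify)) {
    cl <- cfg$classify
    mdir <- cl$model %||% res$train %||% file.path(out_dir, "model")
    fm_paths <- if (!is.null(cl$batch))
      list.files(cl$batch, pattern = "\\.knn$", full.names = TRUE)
    else res$featurize %||%
      list.files(file.path(out_dir, "fields"), pattern = "\\.knn$",
                 full.names = TRUE)
    meta <- jsonlite::fromJSON(file.path(mdir, "spec.json"),
                               simplifyVector = FALSE)
    for (p in fm_paths) {      # pre-flight: fail before loading weights
      hdr <- peek_features_header(p)
      if (hdr$k != meta$spec$input_k)
        abort_param(paste0(
          "stage incompatibility: model '%s' expects k = %d but '%s' ",
          "holds k = %d features"),
          meta$spec$name, meta$spec$input_k, basename(p), hdr$k)
    }
    model <- load_model(mdir)
    outs <- character(0)
    for (p in fm_paths) {
      fm <- read_features(p)
      pl <- classify_points(model, fm,
                            threshold = cl$threshold %||% 0.5)
      tab <- read_localizations(sub("\\.knn$", ".csv", p))
      tab$score <- pl$scores[, ncol(pl$scores)]
      tab$label <- pl$label
      op <- sub("\\.knn$", "_labels.csv", p)
      write_localizations(tab, op,
                          sidecar = list(model = meta$spec$name, seed = seed))
      outs <- c(outs, op)
    }
    log_stage("classify: annotated %d file(s)", length(outs))
    res$classify <- outs
  }

  if (!is.null(cfg$segment)) {
    sg <- cfg$segment
    in_paths <- if (!is.null(sg$batch))
      list.files(sg$batch, pattern = "_labels\\.csv$", full.names = TRUE)
    else res$classify %||%
      list.files(file.path(out_dir, "fields"), pattern = "_labels\\.csv$",
                 full.names = TRUE)
    outs <- character(0)
    for (p in in_paths) {
      tab <- read_localizations(p)
      seg <- segment_points(tab, tab$label,
                            min_cluster_size = sg$min_cluster_size %||% 3L,
                            k = sg$k %||% 100L)
      shp <- cluster_shapes(tab, seg,
                            disc_factor = sg$disc_factor %||% 1,
                            erosion_factor = sg$erosion_factor %||% 0.5)
      tab$cluster_id <- seg$cluster_id
      write_localizations(tab, sub("_labels\\.csv$", "_segmented.csv", p))
      ct <- data.frame(
        cluster_id = as.integer(names(seg$clusters)),
        n_points = lengths(seg$clusters),
        area_nm2 = vapply(shp, function(s) s$area_nm2, numeric(1)),
        centroid_x = vapply(seg$clusters, function(ix) mean(tab$x[ix]),
                            numeric(1)),
        centroid_y = vapply(seg$clusters, function(ix) mean(tab$y[ix]),
                            numeric(1)))
      cp <- sub("_labels\\.csv$", "_clusters.csv", p)
      write.csv(ct, cp, row.names = FALSE)
      write_sidecar(cp, list(seed = seed, source = basename(p)))
      writeLines(shapes_wkt(shp),
                 sub("_labels\\.csv$", "_outlines.wkt", p))
      outs <- c(outs, cp)
    }
    log_stage("segment: %d file(s)", length(outs))
    res$segment <- outs
  }

  if (!is.null(cfg$report)) {
    rp <- cfg$report
    seg_paths <- res$segment %||%
      list.files(file.path(out_dir, "fields"), pattern = "_clusters\\.csv$",
                 full.names = TRUE)
    rows <- lapply(seg_paths, function(p) {
      ct <- read.csv(p)
      pts <- read_localizations(sub("_clusters\\.csv$", "_segmented.csv", p))
      area <- if (isTRUE(rp$area_from_hull)) hull_area_um2(pts) else
        as.numeric(rp$analysis_area_um2 %||% hull_area_um2(pts))
      data.frame(field = basename(p),
                 n_clusters = nrow(ct),
                 clusters_per_um2 = nrow(ct) / area,
                 pct_points_clustered = 100 * sum(pts$cluster_id > 0) /
                   nrow(pts),
                 median_points_per_cluster = median(ct$n_points),
                 median_area_nm2 = median(ct$area_nm2))
    })
    rep_df <- do.call(rbind, rows)
    rp_path <- file.path(out_dir, "report.csv")
    write.csv(rep_df, rp_path, row.names = FALSE)
    write_sidecar(rp_path, list(seed = seed))
    log_stage("report: %d field(s) aggregated", nrow(rep_df))
    res$report <- rp_path
  }
  invisible(res)
}
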