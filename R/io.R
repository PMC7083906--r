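#' Localization-table CSV dialects
#'
#' A dialect maps file columns onto the pipeline's canonical `point_id`,
#' `x`, `y`, `z` fields and states the unit of stored coordinates.
#' The default is the ThunderSTORM export convention (`"x [nm]"`,
#' `"y [nm]"`, optional `"z [nm]"`; an `"uncertainty [nm]"` column is
#' tolerated but ignored, as localization precision is not used by the
#' models).  Coordinates stored in pixels are converted with
#' `pixel_size_nm`.
#'
#' @param x,y,z,id Column names in the file (`z`/`id` optional, `NA` to
#'   disable).
#' @param unit `"nm"` or `"px"`.
#' @param pixel_size_nm Pixel pitch for `unit = "px"`.
#' @param delim Field delimiter.
#' @return A `table_dialect` list.
#' @export
table_dialect <- function(x, y, z = NA_character_, id = NA_character_,
                          unit = c("nm", "px"), pixel_size_nm = NA_real_,
                          delim = ",") {
  unit <- match.arg(unit)
  if (unit == "px" && (!is.finite(pixel_size_nm) || pixel_size_nm <= 0))
    abort_param("pixel-unit dialects need a positive pixel_size_nm")
  structure(list(x = x, y = y, z = z, id = id, unit = unit,
                 pixel_size_nm = pixel_size_nm, delim = delim),
            class = "table_dialect")
}

#' @rdname table_dialect
#' @export
thunderstorm_dialect <- function() {
  table_dialect(x = "x [nm]", y = "y [nm]", z = "z [nm]", id = "id")
}

#' @rdname table_dialect
#' @export
generic_dialect <- function() table_dialect(x = "x", y = "y", z = "z")

#' Read a localization table
#'
#' Reads a delimited localization file under a [table_dialect()],
#' converting coordinates to nanometres and preserving row order.  When
#' the file has no id column, `point_id` is assigned from file order.
#' Rows with missing or non-finite coordinates are dropped with a
#' message reporting the count.
#'
#' @param path CSV path.
#' @param dialect A `table_dialect`; the ThunderSTORM convention is
#'   tried first by default, falling back to generic `x,y[,z]` headers.
#' @return Localization data.frame (`point_id`, `x`, `y`\[, `z`\], nm).
#' @export
read_localizations <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort_param("file not found: %s", path)
  try_dialects <- if (is.null(dialect))
    list(thunderstorm_dialect(), generic_dialect()) else list(dialect)
  df <- read.csv(path, check.names = FALSE,
                 sep = try_dialects[[1]]$delim %||% ",")
  d <- NULL
  for (cand in try_dialects) {
    if (all(c(cand$x, cand$y) %in% names(df))) { d <- cand; break }
  }
  if (is.null(d))
    abort_param("no x/y columns matching the dialect; file headers: %s",
                paste(names(df), collapse = ", "))
  scale <- if (d$unit == "px") d$pixel_size_nm else 1
  out <- data.frame(x = as.numeric(df[[d$x]]) * scale,
                    y = as.numeric(df[[d$y]]) * scale)
  if (!is.na(d$z) && d$z %in% names(df))
    out$z <- as.numeric(df[[d$z]]) * scale
  out$point_id <- if (!is.na(d$id) && d$id %in% names(df))
    as.integer(df[[d$id]]) else seq_len(nrow(out))
  ok <- rowSums(!is.finite(as.matrix(out[, intersect(c("x", "y", "z"),
                                                     names(out))]))) == 0
  if (any(!ok))
    message(sprintf("dropped %d malformed row(s) from %s", sum(!ok), path))
  # ground-truth / annotation columns survive a round trip
  for (cn in intersect(c("label", "true_cluster_id", "score", "cluster_id"),
                       names(df)))
    out[[cn]] <- df[[cn]]
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0) abort_param("no valid localization rows in %s", path)
  rownames(out) <- NULL
  out[, c("point_id", intersect(c("x", "y", "z"), names(out)),
          intersect(c("label", "true_cluster_id", "score", "cluster_id"),
                    names(out)))]
}

#' Write a localization table (ThunderSTORM-style headers)
#'
#' @param table Localization data.frame (`x`, `y`\[, `z`\] in nm; extra
#'   columns such as `label`, `score` or `cluster_id` are passed
#'   through).
#' @param path Output CSV path.
#' @param sidecar Optional named list merged into the JSON provenance
#'   sidecar written next to the file.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, sidecar = NULL) {
  out <- data.frame(id = table$point_id %||% seq_len(nrow(table)),
                    check.names = FALSE)
  out[["x [nm]"]] <- table$x
  out[["y [nm]"]] <- table$y
  if (!is.null(table$z)) out[["z [nm]"]] <- table$z
  for (cn in setdiff(names(table), c("point_id", "x", "y", "z")))
    out[[cn]] <- table[[cn]]
  # 17 significant digits keep the nm coordinates bit-exact on re-read
  for (cn in names(out))
    if (is.double(out[[cn]]))
      out[[cn]] <- sprintf("%.17g", out[[cn]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, sidecar)
  invisible(path)
}

# Provenance sidecar: every output file gets <file>.json with tool
# version, seed (when known) and upstream file hashes.
write_sidecar <- function(path, extra = NULL) {
  info <- c(list(
    tool = "smlmclust",
    version = as.character(utils::packageVersion("smlmclust")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    file = basename(path),
    md5 = unname(tools::md5sum(path))
  ), extra)
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(info)
}

#' Write a simulated field with its ground truth
#'
#' Emits `id,x [nm],y [nm][,z [nm]],label,true_cluster_id` plus a JSON
#' sidecar recording the scenario, the cell polygon and the seed.
#'
#' @param field A `sim_field` from [simulate_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  tab <- field$table
  tab$label <- field$truth$label
  tab$true_cluster_id <- field$truth$true_cluster_id
  write_localizations(tab, path, sidecar = list(
    seed = field$seed,
    scenario = unclass(field$scenario),
    cell = list(area_um2 = field$cell$area_um2,
                vertices = field$cell$vertices,
                seed = field$cell$seed,
                mean_diameter_um = field$cell$mean_diameter_um,
                irregularity = field$cell$irregularity)))
  invisible(path)
}
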