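#' Write a grid to disk
#'
#' Stores the values as a single-band TIFF (32-bit float for continuous
#' grids, 8-bit for integer class grids) with a JSON sidecar
#' (`<path>.json`) carrying the georeferencing: cell size, origin, CRS note,
#' nodata convention and value kind. The pair round-trips through
#' [read_grid()].
#'
#' @param grid A `depth_grid` (continuous values or integer class codes).
#' @param path Output path (conventionally `.tif`).
#' @param kind `"float"` (default) or `"class"` for integer-coded class
#'   grids (codes 0-255; `NA` stored as 0).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, kind = c("float", "class")) {
  stopifnot(is_depth_grid(grid))
  kind <- match.arg(kind)
  v <- grid$values
  if (kind == "class") {
    codes <- v
    codes[is.na(codes)] <- 0
    if (any(codes < 0 | codes > 255 | codes != round(codes)))
      stop("class grids must hold integer codes in 0..255")
    tiff::writeTIFF(codes / 255, path, bits.per.sample = 8L)
    scale <- NULL
  } else {
    # 32-bit samples must lie in [0, 1]; store range-scaled values and
    # record the affine scale in the sidecar (exact to single precision)
    rng <- range(v, na.rm = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
    vv <- (v - rng[1]) / (rng[2] - rng[1])
    vv[is.na(vv)] <- 0
    tiff::writeTIFF(vv, path, bits.per.sample = 32L)
    scale <- rng
  }
  sidecar <- list(cell = grid$cell, origin = grid$origin, crs = grid$crs,
                  kind = kind, scale = scale,
                  nodata_mask = if (kind == "float" && anyNA(v))
                    which(is.na(v)) else NULL,
                  labels = attr(grid, "labels"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path Path to the TIFF; the `<path>.json` sidecar must exist
#'   (missing georeferencing is an error).
#' @return A `depth_grid`; class grids carry the stored `labels` attribute.
#' @export
read_grid <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing georeferencing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  if (identical(meta$kind, "class")) {
    v <- round(v * 255)
    v[v == 0] <- NA
    storage.mode(v) <- "integer"
  } else {
    v <- meta$scale[1] + v * (meta$scale[2] - meta$scale[1])
    if (!is.null(meta$nodata_mask)) v[meta$nodata_mask] <- NA_real_
  }
  g <- depth_grid(v, meta$cell, meta$origin, meta$crs)
  if (!is.null(meta$labels)) attr(g, "labels") <- meta$labels
  g
}

#' Write / read an observation table as CSV
#'
#' Plain UTF-8 CSV with header `x,y,depth_m,class,source,role` plus any
#' joined predictor columns.
#'
#' @param table Observation table.
#' @param path Output CSV path.
#' @return `path` invisibly ([write_observations()]); the table with
#'   `class` as a factor ([read_observations()]).
#' @export
write_observations <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("class" %in% names(out))
    out$class <- factor(out$class, levels = substrate_classes())
  out
}

#' Observation inventory of the British Columbia substrate compilation
#'
#' Returns the published inventory of substrate observations (counts by
#' role, sampling type, source agency and class) for the Pacific-shelf
#' compilation whose sampling structure the synthetic samplers emulate:
#' grab, dive, ROV and marsh records for model building, and dive, camera
#' and ROV sets for independent evaluation.
#'
#' @return Data frame with columns `role, type, source, n, Rock, Mixed,
#'   Sand, Mud`; `*_totals` rows carry the published totals.
#' @export
observation_inventory <- function() {
  path <- system.file("extdata", "bc_observation_counts.csv",
                      package = "benthoscape")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute and reconcile the observation-inventory totals
#'
#' Sums the component rows of [observation_inventory()] per role and checks
#' them against the published totals rows: the data ledger must reconcile
#' exactly before the counts are used (e.g. to parameterise samplers or
#' class weights).
#'
#' @return List with data frames `computed` and `printed` (per-class and
#'   grand totals by role) and logical `reconciled`.
#' @export
inventory_ledger <- function() {
  inv <- observation_inventory()
  is_total <- grepl("_totals$", inv$role)
  comp <- inv[!is_total, ]
  printed <- inv[is_total, ]
  cols <- c("n", substrate_classes())
  computed <- do.call(rbind, lapply(c("build", "evaluation"), function(r) {
    s <- colSums(comp[comp$role == r, cols, drop = FALSE])
    data.frame(role = paste0(r, "_totals"), t(s), stringsAsFactors = FALSE)
  }))
  printed <- printed[, c("role", cols)]
  rownames(printed) <- rownames(computed) <- NULL
  list(computed = computed, printed = printed,
       reconciled = isTRUE(all.equal(computed[, cols], printed[, cols],
                                     check.attributes = FALSE)))
}

# FNV-1a hash of a serialised R object (run-manifest identity).
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
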