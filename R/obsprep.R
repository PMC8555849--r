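#' Reclassify source substrate labels to the four bottom-type classes
#'
#' Applies a total mapping from source-specific labels to Rock, Mixed, Sand,
#' Mud. Labels mapped to `"drop"` are removed (and counted); an unmapped
#' label is an error naming the label, so silent loss is impossible.
#'
#' @param table Observation table with a `class` column of source labels.
#' @param map Named character vector: `source label -> class` where class is
#'   one of the four substrate classes or `"drop"`.
#' @return The table with `class` as a factor over the four classes. The
#'   attribute `ledger` records rows in / out / dropped.
#' @export
reclassify <- function(table, map) {
  stopifnot(is.data.frame(table), "class" %in% names(table))
  labels <- as.character(table$class)
  unknown <- setdiff(unique(labels), names(map))
  if (length(unknown))
    stop("unmapped substrate label(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(unique(map), c(substrate_classes(), "drop"))
  if (length(bad))
    stop("map targets must be the four classes or 'drop'; got: ",
         paste(bad, collapse = ", "))
  mapped <- unname(map[labels])
  keep <- mapped != "drop"
  out <- table[keep, , drop = FALSE]
  out$class <- factor(mapped[keep], levels = substrate_classes())
  rownames(out) <- NULL
  attr(out, "ledger") <- c(rows_in = nrow(table), rows_out = nrow(out),
                           dropped = sum(!keep))
  out
}

#' Aggregate observations to one record per grid cell by modal class
#'
#' Collapses all points falling in the same cell of `geometry` into a single
#' record at the cell centre, carrying the modal substrate class (ties
#' broken by the fixed priority Rock > Mixed > Sand > Mud) and the mean of
#' the point depths. This is how densely sampled transect/quadrat surveys
#' are reduced to the analysis resolution.
#'
#' @param table Observation table (`x, y, depth_m, class, source, role`).
#' @param geometry A `depth_grid` defining the cells; all points must fall
#'   inside its extent.
#' @return Aggregated observation table, one row per occupied cell.
#' @export
aggregate_mode <- function(table, geometry) {
  stopifnot(is.data.frame(table), is_depth_grid(geometry))
  if (nrow(table) == 0) stop("empty input")
  rc <- cell_at(geometry, table$x, table$y)
  if (anyNA(rc$row)) stop("points fall outside the grid extent")
  key <- (rc$row - 1L) * ncol(geometry$values) + rc$col
  cls <- factor(as.character(table$class), levels = substrate_classes())
  if (anyNA(cls)) stop("classes must already be the four substrate classes")
  parts <- split(seq_len(nrow(table)), key)
  rows <- lapply(parts, function(idx) {
    counts <- table(cls[idx])
    # modal class; ties resolved by class priority (Rock first), which is
    # the order of the factor levels
    mode_cls <- names(counts)[which.max(counts)]
    data.frame(class = mode_cls, depth_m = mean(table$depth_m[idx]),
               source = as.character(table$source[idx][1]),
               role = as.character(table$role[idx][1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keys <- as.integer(names(parts))
  row <- (keys - 1L) %/% ncol(geometry$values) + 1L
  col <- (keys - 1L) %% ncol(geometry$values) + 1L
  ctr <- cell_xy(geometry, row, col)
  out <- cbind(data.frame(x = ctr$x, y = ctr$y), out)
  out$class <- factor(out$class, levels = substrate_classes())
  rownames(out) <- NULL
  attr(out, "ledger") <- c(rows_in = nrow(table), rows_out = nrow(out),
                           dropped = 0L)
  out
}

#' Screen observations against the bathymetry by depth discrepancy
#'
#' Removes rows whose recorded depth differs from the bathymetry at the
#' point by more than `max_diff` metres -- the screen used to catch drifted
#' drop-camera positions and similar positional errors.
#'
#' @param table Observation table.
#' @param bathy A `depth_grid` covering the points.
#' @param max_diff Maximum absolute discrepancy (m); default 50.
#' @return The screened table, with a `ledger` attribute; warns if nothing
#'   survives.
#' @export
screen_depth <- function(table, bathy, max_diff = 50) {
  stopifnot(is.data.frame(table), is_depth_grid(bathy))
  grid_depth <- extract_at(bathy, table$x, table$y)
  keep <- !is.na(grid_depth) & abs(table$depth_m - grid_depth) <= max_diff
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0 && nrow(table) > 0)
    warning("depth screening removed every observation")
  attr(out, "ledger") <- c(rows_in = nrow(table), rows_out = nrow(out),
                           dropped = sum(!keep))
  out
}

#' Join predictor values onto observations
#'
#' Adds one column per predictor layer, valued at the cell containing each
#' point. Multiple observations in one cell each keep their own row with
#' identical predictor values, preserving the observational sample size.
#' Observations on nodata (e.g. land) cells are dropped and counted.
#'
#' @param table Observation table.
#' @param stack A `predictor_stack` covering the points.
#' @return The table with predictor columns appended; `ledger` attribute
#'   reconciles rows in = rows out + dropped.
#' @export
join_predictors <- function(table, stack) {
  stopifnot(is.data.frame(table), inherits(stack, "predictor_stack"))
  pv <- extract_stack(stack, table$x, table$y)
  complete <- stats::complete.cases(pv)
  out <- cbind(table[complete, , drop = FALSE], pv[complete, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "ledger") <- c(rows_in = nrow(table), rows_out = nrow(out),
                           dropped = sum(!complete))
  out
}

#' Random train/test split of the build data
#'
#' Simple (unstratified) random partition into training and testing sets,
#' sized `round(n * train_frac)` and the remainder; deterministic given the
#' seed.
#'
#' @param table Observation table with at least 2 rows.
#' @param train_frac Training proportion in (0, 1); default 0.67.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_build <- function(table, train_frac = 0.67, seed = 1) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  if (n < 2) stop("need at least 2 rows to split")
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be in (0, 1)")
  with_seed(seed, {
    n_train <- round(n * train_frac)
    n_train <- min(max(n_train, 1L), n - 1L)
    idx <- sample.int(n, n_train)
    list(train = table[idx, , drop = FALSE],
         test = table[-idx, , drop = FALSE])
  })
}

#' Depth zone labels, in order
#' @return Character vector of the eight ordered zones.
#' @export
depth_zones <- function() {
  c("Intertidal", "0-5m", "5-10m", "10-20m", "20-50m", "50-100m",
    "100-200m", "200m+")
}

#' Assign depths to ecological depth zones
#'
#' Intertidal for depths at or above chart datum (depth <= 0), then
#' half-open zones (0,5], (5,10], (10,20], (20,50], (50,100], (100,200] and
#' (200, Inf) metres, upper bound inclusive.
#'
#' @param depth Numeric vector of depths (m, positive down); must be finite.
#' @return Ordered factor over [depth_zones()].
#' @export
assign_zone <- function(depth) {
  if (any(!is.finite(depth))) stop("depths must be finite")
  brk <- c(-Inf, 0, 5, 10, 20, 50, 100, 200, Inf)
  factor(depth_zones()[findInterval(depth, brk, left.open = TRUE,
                                    rightmost.closed = TRUE)],
         levels = depth_zones(), ordered = TRUE)
}
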