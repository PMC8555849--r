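#' Depth grid container
#'
#' A regular 2-D grid of depths with minimal georeferencing. Values are in
#' metres, positive downward (chart-datum convention): marine cells have
#' depth > 0, land cells carry negative depths (elevations above datum) and
#' are *not* nodata, so shoreline derivatives remain defined. `NA` marks
#' true nodata. Row 1 is the northernmost row; `origin` is the (x, y) of the
#' grid's lower-left corner in metres.
#'
#' @param values Numeric matrix (rows x cols) of depths (m, positive down).
#' @param cell Cell size in metres (> 0).
#' @param origin Numeric length-2: x, y of the lower-left corner (m).
#' @param crs Character note on the coordinate system.
#' @return An object of class `depth_grid`.
#' @export
depth_grid <- function(values, cell, origin = c(0, 0), crs = "local-cartesian") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell) || cell <= 0)
    stop("`cell` must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be two finite numbers")
  structure(
    list(values = values, cell = as.numeric(cell),
         origin = as.numeric(origin), crs = as.character(crs)[1]),
    class = "depth_grid"
  )
}

#' @export
print.depth_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<depth_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell, x$origin[1], x$origin[2]))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  depth range [%0.2f, %0.2f] m; marine %0.1f%%; nodata %d cells\n",
              rng[1], rng[2], 100 * mean(v > 0, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Test for depth_grid
#' @param x Object.
#' @return Logical.
#' @export
is_depth_grid <- function(x) inherits(x, "depth_grid")

#' Make a grid sharing another grid's geometry
#' @param g A `depth_grid` supplying the geometry.
#' @param values Matrix of the same dimensions.
#' @return A `depth_grid` with `g`'s geometry and the new values.
#' @export
grid_like <- function(g, values) {
  stopifnot(is_depth_grid(g))
  if (!identical(dim(values), dim(g$values)))
    stop("replacement values have different dimensions")
  depth_grid(values, g$cell, g$origin, g$crs)
}

#' Do two grids share a geometry?
#' @param a,b `depth_grid` objects.
#' @param tol Numeric tolerance on cell size and origin (m).
#' @return Logical.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  is_depth_grid(a) && is_depth_grid(b) &&
    identical(dim(a$values), dim(b$values)) &&
    abs(a$cell - b$cell) < tol && all(abs(a$origin - b$origin) < tol)
}

#' Marine mask of a grid
#' @param g A `depth_grid`.
#' @return Logical matrix: TRUE where depth > 0 (submerged, not nodata).
#' @export
marine_mask <- function(g) {
  stopifnot(is_depth_grid(g))
  m <- g$values > 0
  m[is.na(m)] <- FALSE
  m
}

# Cell-centre coordinates for (row, col) index vectors.
cell_xy <- function(g, row, col) {
  nr <- nrow(g$values)
  list(x = g$origin[1] + (col - 0.5) * g$cell,
       y = g$origin[2] + (nr - row + 0.5) * g$cell)
}

# Containing cell (row, col) for point coordinates; NA outside the grid.
cell_at <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$origin[1]) / g$cell) + 1L
  row <- nr - floor((y - g$origin[2]) / g$cell)
  bad <- !is.finite(col) | !is.finite(row) | col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# Grid values at point coordinates (nearest cell); NA outside.
extract_at <- function(g, x, y) {
  rc <- cell_at(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Aggregate a grid to coarser cells by block statistics
#'
#' Aggregates `factor` x `factor` blocks of cells into one coarse cell
#' (default: block mean), the standard way a fine bathymetry is degraded to
#' a coarser analysis resolution. Trailing rows/columns that do not fill a
#' complete block are dropped.
#'
#' @param g A `depth_grid`.
#' @param factor Integer >= 2 aggregation factor.
#' @param fun Summary function applied to each block (default `mean`).
#' @return A `depth_grid` with cell size `factor * g$cell`.
#' @export
block_aggregate <- function(g, factor, fun = mean) {
  stopifnot(is_depth_grid(g))
  f <- as.integer(factor)
  if (is.na(f) || f < 2L) stop("`factor` must be an integer >= 2")
  v <- g$values
  nr <- (nrow(v) %/% f) * f
  nc <- (ncol(v) %/% f) * f
  if (nr < f || nc < f) stop("grid too small for this aggregation factor")
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  # fold each block into a column of a (f*f) x (nr/f * nc/f) matrix
  a <- array(v, dim = c(f, nr %/% f, f, nc %/% f))
  coarse <- apply(a, c(2, 4), fun)
  # origin: keep lower-left; dropped rows are at the top (north), so the
  # lower-left corner moves only if rows were dropped
  oy <- g$origin[2]
  depth_grid(coarse, g$cell * f, c(g$origin[1], oy), g$crs)
}

#' Predictor stack
#'
#' A named set of co-registered predictor layers sharing one grid geometry.
#'
#' @param layers Named list of numeric matrices, all the same dimensions.
#' @param geometry A `depth_grid` supplying geometry (its values are ignored).
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, geometry) {
  stopifnot(is_depth_grid(geometry))
  if (!is.list(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a fully named list")
  if (anyDuplicated(names(layers))) stop("duplicate layer names")
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dim(geometry$values)))
      stop(sprintf("layer '%s' does not match the stack geometry", nm))
  }
  structure(list(layers = layers, geometry = geometry),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("<predictor_stack> %d layers on %d x %d grid @ %g m\n",
              length(x$layers), nrow(x$geometry$values),
              ncol(x$geometry$values), x$geometry$cell))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Layer names of a stack
#' @param x A `predictor_stack`.
#' @return Character vector.
#' @export
stack_layers <- function(x) names(x$layers)

# Data frame of predictor values at point coordinates (one column per layer).
extract_stack <- function(stack, x, y) {
  g <- stack$geometry
  rc <- cell_at(g, x, y)
  out <- lapply(stack$layers, function(v) {
    val <- rep(NA_real_, length(x))
    ok <- !is.na(rc$row)
    val[ok] <- v[cbind(rc$row[ok], rc$col[ok])]
    val
  })
  as.data.frame(out, optional = TRUE)
}
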