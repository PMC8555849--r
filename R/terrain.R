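#' @keywords internal
# Neighbour shift with edge replication; NA neighbours fall back to the
# centre value so shoreline windows stay defined.
shift_pad <- function(v, dr, dc) {
  nr <- nrow(v); nc <- ncol(v)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  out <- v[ri, ci, drop = FALSE]
  bad <- is.na(out) & !is.na(v)
  out[bad] <- v[bad]
  out
}

# NA-aware focal mean with an arbitrary (odd-dimension, symmetric) kernel,
# computed by FFT convolution with zero padding, so edge cells average over
# the partial window that fits on the grid.
focal_mean_kernel <- function(v, kernel) {
  nk <- dim(kernel)
  stopifnot(all(nk %% 2 == 1))
  nr <- nrow(v); nc <- ncol(v)
  pr <- nextn(nr + nk[1] - 1L, c(2, 3, 5))
  pc <- nextn(nc + nk[2] - 1L, c(2, 3, 5))
  pad <- function(m) {
    out <- matrix(0, pr, pc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  v0 <- v; v0[is.na(v0)] <- 0
  msk <- matrix(as.numeric(!is.na(v)), nr, nc)
  fk <- fft(pad(kernel))
  conv <- function(m) {
    full <- Re(fft(fft(pad(m)) * fk, inverse = TRUE)) / (pr * pc)
    off <- (nk - 1L) %/% 2L
    full[off[1] + seq_len(nr), off[2] + seq_len(nc), drop = FALSE]
  }
  num <- conv(v0)
  den <- conv(msk)
  out <- num / den
  out[den < 0.5] <- NA_real_
  out[is.na(v)] <- NA_real_
  out
}

# Annulus indicator kernel: inner < distance (cells) <= outer.
annulus_kernel <- function(inner, outer) {
  r <- ceiling(outer)
  d <- sqrt(outer((-r:r)^2, (-r:r)^2, `+`))
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  k[d > inner & d <= outer] <- 1
  k
}

#' Local terrain derivatives of a bathymetry
#'
#' Derives one of the classic 3 x 3 window terrain metrics. Derivatives are
#' computed on elevation (the negated depth), with edge replication so
#' shoreline and boundary cells keep defined values; land cells carry
#' elevations and participate in their marine neighbours' windows.
#'
#' \describe{
#'   \item{slope}{Horn finite-difference gradient magnitude, degrees.}
#'   \item{curvature}{Zevenbergen-Thorne general curvature, signed, in
#'     1/100 m units (positive = convex-up).}
#'   \item{slope_sd}{Focal standard deviation of Horn slope in a 3 x 3
#'     window, degrees.}
#'   \item{rugosity}{Triangulated surface-area to planar-area ratio over
#'     the 3 x 3 window (>= 1; 1 = flat).}
#' }
#'
#' @param bathy A `depth_grid` of at least 3 x 3 cells.
#' @param metric One of `"slope"`, `"curvature"`, `"slope_sd"`, `"rugosity"`.
#' @return A `depth_grid` holding the derivative; nodata propagated.
#' @export
derive_local <- function(bathy,
                         metric = c("slope", "curvature", "slope_sd",
                                    "rugosity")) {
  stopifnot(is_depth_grid(bathy))
  metric <- match.arg(metric)
  v <- bathy$values
  if (nrow(v) < 3 || ncol(v) < 3) stop("grid must be at least 3 x 3")
  if (all(is.na(v))) stop("all-nodata grid")
  z <- -v  # elevation
  L <- bathy$cell
  out <- switch(metric,
    slope = horn_slope(z, L),
    curvature = {
      zn <- shift_pad(z, -1L, 0L); zs <- shift_pad(z, 1L, 0L)
      zw <- shift_pad(z, 0L, -1L); ze <- shift_pad(z, 0L, 1L)
      d2x <- ((zw + ze) / 2 - z) / L^2
      d2y <- ((zn + zs) / 2 - z) / L^2
      -2 * (d2x + d2y) * 100
    },
    slope_sd = {
      s <- horn_slope(z, L)
      m1 <- focal_mean_kernel(s, matrix(1, 3, 3))
      m2 <- focal_mean_kernel(s^2, matrix(1, 3, 3))
      sqrt(pmax(m2 - m1^2, 0))
    },
    rugosity = jenness_rugosity(z, L)
  )
  out[is.na(v)] <- NA_real_
  grid_like(bathy, out)
}

horn_slope <- function(z, L) {
  zn  <- shift_pad(z, -1L,  0L); zs  <- shift_pad(z, 1L,  0L)
  zw  <- shift_pad(z,  0L, -1L); ze  <- shift_pad(z, 0L,  1L)
  znw <- shift_pad(z, -1L, -1L); zne <- shift_pad(z, -1L, 1L)
  zsw <- shift_pad(z,  1L, -1L); zse <- shift_pad(z,  1L, 1L)
  p <- ((zne + 2 * ze + zse) - (znw + 2 * zw + zsw)) / (8 * L)
  q <- ((znw + 2 * zn + zne) - (zsw + 2 * zs + zse)) / (8 * L)
  atan(sqrt(p^2 + q^2)) * 180 / pi
}

# Surface-area ratio from the eight triangles joining the cell centre to
# the midpoints of segments toward its neighbours (Jenness-style).
jenness_rugosity <- function(z, L) {
  dirs <- list(n  = c(-1L, 0L), ne = c(-1L, 1L), e  = c(0L, 1L),
               se = c(1L, 1L),  s  = c(1L, 0L),  sw = c(1L, -1L),
               w  = c(0L, -1L), nw = c(-1L, -1L))
  planar <- c(L, L * sqrt(2), L, L * sqrt(2), L, L * sqrt(2), L, L * sqrt(2))
  zk <- lapply(dirs, function(d) shift_pad(z, d[1], d[2]))
  half_edge <- Map(function(zz, pl) sqrt(pl^2 + (zz - z)^2) / 2, zk, planar)
  ring <- c(1:8, 1)
  area <- 0
  for (i in 1:8) {
    a <- half_edge[[ring[i]]]
    b <- half_edge[[ring[i + 1]]]
    dz <- zk[[ring[i]]] - zk[[ring[i + 1]]]
    cc <- sqrt(L^2 + dz^2) / 2  # adjacent neighbours are one cell apart
    s <- (a + b + cc) / 2
    area <- area + sqrt(pmax(s * (s - a) * (s - b) * (s - cc), 0))
  }
  area / L^2
}

#' Bathymetric position index specification
#'
#' @param inner,outer Annulus radii in cells, `0 <= inner < outer`.
#' @param label Scale label (`"fine"`, `"medium"`, `"broad"`, or any name).
#' @return An object of class `bpi_spec`.
#' @export
bpi_spec <- function(inner, outer, label = "bpi") {
  if (inner < 0 || inner >= outer) stop("need 0 <= inner < outer")
  structure(list(inner = inner, outer = outer, label = label),
            class = "bpi_spec")
}

#' Bathymetric position index
#'
#' BPI(cell) = mean depth over the annulus `inner < dist <= outer` minus the
#' cell depth, so positive values mark crests (shallower than surroundings)
#' and negative values depressions. Edge cells use the partial annulus that
#' fits on the grid; land cells participate with their elevations.
#'
#' @param bathy A `depth_grid`.
#' @param spec A `bpi_spec`; the outer radius must fit inside the grid.
#' @return A `depth_grid` of BPI values (m).
#' @export
bpi <- function(bathy, spec) {
  stopifnot(is_depth_grid(bathy), inherits(spec, "bpi_spec"))
  v <- bathy$values
  if (2 * ceiling(spec$outer) + 1 > min(dim(v)))
    stop("outer radius does not fit inside the grid")
  k <- annulus_kernel(spec$inner, spec$outer)
  out <- focal_mean_kernel(v, k) - v
  grid_like(bathy, out)
}

#' Fetch specification
#'
#' @param bearings Number of equally spaced compass bearings (>= 8).
#' @param cap Maximum per-bearing distance (m, > 0); open water beyond the
#'   grid or the cap contributes the cap distance.
#' @param step_frac Ray-marching step as a fraction of the cell size.
#' @return An object of class `fetch_spec`.
#' @export
fetch_spec <- function(bearings = 32, cap = 50000, step_frac = 0.5) {
  if (bearings < 8) stop("`bearings` must be >= 8")
  if (cap <= 0) stop("`cap` must be > 0")
  structure(list(bearings = as.integer(bearings), cap = cap,
                 step_frac = step_frac),
            class = "fetch_spec")
}

#' Sum of fetch over compass bearings
#'
#' For every marine cell, sums over equally spaced bearings the ray distance
#' to the first land cell (depth <= 0 or nodata), each ray capped at the cap
#' distance; rays leaving the grid count as open water out to the cap. Land
#' cells are nodata in the result. A proxy for wind-wave exposure.
#'
#' @param bathy A `depth_grid` with at least one marine cell.
#' @param spec A `fetch_spec`.
#' @return A `depth_grid` of summed fetch (m).
#' @export
fetch_sum <- function(bathy, spec = fetch_spec()) {
  stopifnot(is_depth_grid(bathy), inherits(spec, "fetch_spec"))
  if (!any(marine_mask(bathy))) stop("no marine cells")
  out <- fetch_raycast(bathy$values, bathy$cell, spec$bearings, spec$cap,
                       spec$step_frac * bathy$cell)
  grid_like(bathy, out)
}

#' Resample a coarse energy field onto a model grid
#'
#' Bilinear interpolation of a coarser georeferenced field onto the target
#' geometry, masked to the target's marine cells. Beyond the outermost
#' coarse cell centres the interpolation extends linearly, so linear fields
#' are reproduced exactly over the whole target grid.
#'
#' @param coarse A `depth_grid` holding the field at native resolution
#'   (must be coarser than the target).
#' @param target A `depth_grid` supplying the output geometry and marine
#'   mask.
#' @return A `depth_grid` on the target geometry.
#' @export
resample_energy <- function(coarse, target) {
  stopifnot(is_depth_grid(coarse), is_depth_grid(target))
  if (coarse$cell <= target$cell)
    stop("`coarse` must have a larger cell size than `target`")
  if (!identical(coarse$crs, target$crs))
    stop("CRS mismatch between coarse field and target grid")
  # extent overlap check
  cx <- coarse$origin[1] + c(0, ncol(coarse$values) * coarse$cell)
  cy <- coarse$origin[2] + c(0, nrow(coarse$values) * coarse$cell)
  tx <- target$origin[1] + c(0, ncol(target$values) * target$cell)
  ty <- target$origin[2] + c(0, nrow(target$values) * target$cell)
  if (cx[2] <= tx[1] || cx[1] >= tx[2] || cy[2] <= ty[1] || cy[1] >= ty[2])
    stop("non-overlapping extents")
  v <- coarse$values
  nrc <- nrow(v); ncc <- ncol(v)
  nrt <- nrow(target$values); nct <- ncol(target$values)
  # fractional coarse indices of target cell centres (1-based centres)
  xs <- target$origin[1] + (seq_len(nct) - 0.5) * target$cell
  ys <- target$origin[2] + (nrt - seq_len(nrt) + 0.5) * target$cell
  colf <- (xs - coarse$origin[1]) / coarse$cell + 0.5
  rowf <- nrc + 0.5 - (ys - coarse$origin[2]) / coarse$cell
  j0 <- pmin(pmax(floor(colf), 1L), ncc - 1L); tj <- colf - j0
  i0 <- pmin(pmax(floor(rowf), 1L), nrc - 1L); ti <- rowf - i0
  v00 <- v[i0, j0, drop = FALSE];      v01 <- v[i0, j0 + 1L, drop = FALSE]
  v10 <- v[i0 + 1L, j0, drop = FALSE]; v11 <- v[i0 + 1L, j0 + 1L, drop = FALSE]
  TI <- matrix(ti, nrt, nct); TJ <- matrix(tj, nrt, nct, byrow = TRUE)
  out <- (1 - TI) * (1 - TJ) * v00 + (1 - TI) * TJ * v01 +
    TI * (1 - TJ) * v10 + TI * TJ * v11
  out[!marine_mask(target)] <- NA_real_
  grid_like(target, out)
}

#' Assemble the predictor stack for a model resolution
#'
#' Derives the full predictor suite from a bathymetry and attaches the
#' resampled energy fields: depth, slope, curvature, slope standard
#' deviation, rugosity, fine/medium/broad BPI, tidal speed, circulation,
#' and -- for the regional (fine) configuration only -- fetch. The coastwide
#' (coarse) configuration omits fetch, whose shallow-water signal is not
#' resolvable at that scale. BPI radii are set in metres and converted to
#' cells, keeping the metric footprint constant across resolutions. All
#' layers are masked to the marine extent.
#'
#' @param bathy A `depth_grid`.
#' @param tide,circulation Coarse energy fields (`depth_grid`s) to resample,
#'   or already co-registered grids.
#' @param resolution `"regional"` (includes fetch) or `"coastwide"`.
#' @param bpi_radii_m Named numeric: outer annulus radii in metres for the
#'   `fine`, `medium` and `broad` BPI.
#' @param fspec A `fetch_spec` (regional only).
#' @return A `predictor_stack`.
#' @export
build_stack <- function(bathy, tide, circulation,
                        resolution = c("regional", "coastwide"),
                        bpi_radii_m = c(fine = 100, medium = 500,
                                        broad = 2500),
                        fspec = fetch_spec()) {
  stopifnot(is_depth_grid(bathy))
  resolution <- match.arg(resolution)
  marine <- marine_mask(bathy)
  mask <- function(m) { m[!marine] <- NA_real_; m }
  cells_of <- function(r_m) max(1L, as.integer(round(r_m / bathy$cell)))
  reg <- function(g) {
    if (same_geometry(g, bathy)) g$values else resample_energy(g, bathy)$values
  }
  layers <- list(
    depth = mask(bathy$values),
    slope = mask(derive_local(bathy, "slope")$values),
    curvature = mask(derive_local(bathy, "curvature")$values),
    slope_sd = mask(derive_local(bathy, "slope_sd")$values),
    rugosity = mask(derive_local(bathy, "rugosity")$values),
    bpi_fine = mask(bpi(bathy, bpi_spec(0, cells_of(bpi_radii_m[["fine"]]),
                                        "fine"))$values),
    bpi_medium = mask(bpi(bathy, bpi_spec(0, cells_of(bpi_radii_m[["medium"]]),
                                          "medium"))$values),
    bpi_broad = mask(bpi(bathy, bpi_spec(0, cells_of(bpi_radii_m[["broad"]]),
                                         "broad"))$values),
    tide = mask(reg(tide)),
    circulation = mask(reg(circulation))
  )
  if (resolution == "regional")
    layers$fetch <- mask(fetch_sum(bathy, fspec)$values)
  predictor_stack(layers, bathy)
}
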