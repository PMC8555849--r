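#' Parameters for the synthetic shelf bathymetry
#'
#' Defines a shelf-like seafloor: a seaward deepening ramp with a connected
#' landmass along the shoreward edge, a broad-scale ridge/valley field, and
#' fine-scale roughness whose amplitude halves every `decay_scale` metres of
#' depth -- the generator's expression of the observation that seafloor
#' heterogeneity decreases with depth. Depths are positive down; land cells
#' carry negative depths (elevations), not nodata.
#'
#' Defaults describe a 6 x 6 km nearshore tile at 20 m cells reaching past
#' 200 m depth, so every depth zone from intertidal to 200+ m is populated.
#'
#' @param nr,nc Grid dimensions in cells (each >= 16).
#' @param cell Cell size (m).
#' @param shelf_gradient Mean seaward deepening (m depth per km).
#' @param ridge_amplitude Amplitude (m) of the broad-scale ridge field.
#' @param fine_amplitude Fine-roughness amplitude (m) at 0 m depth.
#' @param decay_scale Depth (m) at which fine roughness halves (> 0).
#' @param land_fraction Target proportion of land cells, in [0, 0.5].
#' @param seed Integer seed.
#' @return An object of class `seafloor_params`.
#' @export
seafloor_params <- function(nr = 300, nc = 300, cell = 20,
                            shelf_gradient = 40, ridge_amplitude = 15,
                            fine_amplitude = 8, decay_scale = 10,
                            land_fraction = 0.15, seed = 1) {
  if (nr < 16 || nc < 16) stop("degenerate grid shape: need at least 16 x 16")
  if (cell <= 0) stop("`cell` must be > 0")
  if (decay_scale <= 0) stop("`decay_scale` must be > 0")
  if (land_fraction < 0 || land_fraction > 0.5)
    stop("`land_fraction` must be in [0, 0.5]")
  structure(list(nr = as.integer(nr), nc = as.integer(nc), cell = cell,
                 shelf_gradient = shelf_gradient,
                 ridge_amplitude = ridge_amplitude,
                 fine_amplitude = fine_amplitude,
                 decay_scale = decay_scale,
                 land_fraction = land_fraction, seed = seed),
            class = "seafloor_params")
}

#' Simulate a shelf-like bathymetry
#'
#' Deterministic given the seed. The seaward axis runs west to east
#' (columns); land occupies the shoreward (west) edge. With ridge and fine
#' amplitudes of zero the surface is a pure ramp, strictly deepening
#' seaward. The shoreline is placed so the realised land fraction matches
#' the target up to the jitter contributed by fine-scale roughness.
#'
#' @param params A `seafloor_params`.
#' @return A `depth_grid` (m, positive down; land cells negative).
#' @export
simulate_bathymetry <- function(params) {
  stopifnot(inherits(params, "seafloor_params"))
  p <- params
  with_seed(p$seed, {
    x_km <- ((seq_len(p$nc) - 0.5) * p$cell) / 1000
    ramp <- matrix(p$shelf_gradient * x_km, p$nr, p$nc, byrow = TRUE)
    base <- ramp
    if (p$ridge_amplitude != 0)
      base <- base + p$ridge_amplitude * gaussian_field(p$nr, p$nc, p$nc / 6)
    # place chart datum so that `land_fraction` of the base surface is land
    base <- base - quantile(base, p$land_fraction, names = FALSE)
    depth <- base
    if (p$fine_amplitude != 0) {
      amp <- p$fine_amplitude * 2^(-pmax(base, 0) / p$decay_scale)
      depth <- depth + amp * gaussian_field(p$nr, p$nc, 2)
    }
    depth_grid(depth, p$cell)
  })
}

#' Parameters for the generative substrate truth
#'
#' The truth model assigns each marine cell one of Rock, Mixed, Sand, Mud by
#' thresholding a standardised latent energy index
#' \deqn{E = w_f \hat z(fetch) + w_t \hat z(tide) + w_s \hat z(slope) -
#'       w_d \hat z(depth) + \epsilon,}
#' where \eqn{\hat z} is the rank-normal transform over marine cells and
#' \eqn{\epsilon} is a smooth noise field whose sd halves every
#' `decay_scale` m of depth (patchiness decays with depth). High energy maps
#' to Rock, low to Mud. Label noise flips a cell to a uniformly random other
#' class with the stated probability.
#'
#' @param w_fetch,w_tide,w_slope,w_depth Non-negative weights of the latent
#'   index components.
#' @param thresholds Strictly increasing length-3 numeric: class cut points
#'   on the standardised index (below t1 = Mud, above t3 = Rock).
#' @param noise_sd Sd of the spatial noise field at 0 m depth (unitless, on
#'   the scale of the standardised index).
#' @param decay_scale Depth (m) at which the noise sd halves.
#' @param label_noise Probability in [0, 0.5) of flipping a cell's class.
#' @param seed Integer seed.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(w_fetch = 1, w_tide = 0.7, w_slope = 1,
                         w_depth = 0.8,
                         thresholds = c(-0.8, 0.1, 0.9),
                         noise_sd = 0.6, decay_scale = 10,
                         label_noise = 0.03, seed = 1) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("`thresholds` must be strictly increasing (t1 < t2 < t3)")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("`label_noise` must be in [0, 0.5)")
  if (decay_scale <= 0) stop("`decay_scale` must be > 0")
  structure(list(w_fetch = w_fetch, w_tide = w_tide, w_slope = w_slope,
                 w_depth = w_depth, thresholds = thresholds,
                 noise_sd = noise_sd, decay_scale = decay_scale,
                 label_noise = label_noise, seed = seed),
            class = "truth_params")
}

# rank-normal transform over a logical mask; NA outside
rank_normal <- function(v, mask) {
  out <- matrix(NA_real_, nrow(v), ncol(v))
  vv <- v[mask]
  out[mask] <- qnorm(rank(vv, ties.method = "average") / (length(vv) + 1))
  out
}

#' Simulate substrate truth from bathymetry and energy layers
#'
#' Marine cells get a class code 1 = Rock, 2 = Mixed, 3 = Sand, 4 = Mud;
#' land and nodata cells are `NA`. The returned grid carries two attributes:
#' `bayes`, the Bayes-optimal class grid given the deterministic part of the
#' latent index (the classifier skill ceiling), and `labels`, the class
#' names in code order.
#'
#' @param bathy A `depth_grid`.
#' @param tp A `truth_params`.
#' @param energy A `predictor_stack` co-registered with `bathy`, containing
#'   layers `fetch`, `tide` and `slope`.
#' @return A `depth_grid` whose values are integer class codes.
#' @export
simulate_truth <- function(bathy, tp, energy) {
  stopifnot(is_depth_grid(bathy), inherits(tp, "truth_params"),
            inherits(energy, "predictor_stack"))
  if (!same_geometry(bathy, energy$geometry))
    stop("energy stack is not co-registered with the bathymetry")
  need <- c("fetch", "tide", "slope")
  miss <- setdiff(need, stack_layers(energy))
  if (length(miss))
    stop("missing energy layer(s): ", paste(miss, collapse = ", "))
  marine <- marine_mask(bathy)
  if (!any(marine)) stop("no marine cells")
  depth <- bathy$values

  e_det <- tp$w_fetch * rank_normal(energy$layers$fetch, marine) +
    tp$w_tide * rank_normal(energy$layers$tide, marine) +
    tp$w_slope * rank_normal(energy$layers$slope, marine) -
    tp$w_depth * rank_normal(depth, marine)

  with_seed(tp$seed, {
    nsd <- matrix(0, nrow(depth), ncol(depth))
    nsd[marine] <- tp$noise_sd * 2^(-depth[marine] / tp$decay_scale)
    eps <- if (tp$noise_sd > 0)
      nsd * gaussian_field(nrow(depth), ncol(depth), 3) else nsd

    e <- e_det + eps
    mu <- mean(e[marine]); s <- sd(e[marine])
    if (!is.finite(s) || s == 0) s <- 1
    cuts <- mu + s * tp$thresholds  # thresholds on the standardised index

    code_from_e <- function(ev) {
      # ascending energy: Mud(4) < t1 <= Sand(3) < t2 <= Mixed(2) < t3 <= Rock(1)
      ifelse(ev > cuts[3], 1L, ifelse(ev > cuts[2], 2L,
             ifelse(ev > cuts[1], 3L, 4L)))
    }
    cls <- matrix(NA_integer_, nrow(depth), ncol(depth))
    cls[marine] <- code_from_e(e[marine])

    # Bayes-optimal rule: argmax_k P(t_{k-1} < E_det + eps <= t_k | cell)
    bayes <- matrix(NA_integer_, nrow(depth), ncol(depth))
    ed <- e_det[marine]; sdv <- nsd[marine]
    brk <- c(-Inf, cuts, Inf)
    pk <- sapply(1:4, function(k) {
      lo <- brk[k]; hi <- brk[k + 1]
      ifelse(sdv > 0, pnorm(hi, ed, sdv) - pnorm(lo, ed, sdv),
             as.numeric(ed > lo & ed <= hi))
    })
    # pk columns are Mud..Rock? No: brk ascends, k=1 lowest energy = Mud.
    codes_by_k <- c(4L, 3L, 2L, 1L)
    bayes[marine] <- codes_by_k[max.col(pk, ties.method = "first")]

    if (tp$label_noise > 0) {
      idx <- which(marine)
      flip <- idx[runif(length(idx)) < tp$label_noise]
      if (length(flip)) {
        cur <- cls[flip]
        shift <- sample.int(3L, length(flip), replace = TRUE)
        cls[flip] <- ((cur - 1L + shift) %% 4L) + 1L
      }
    }
    out <- grid_like(bathy, cls)
    attr(out, "bayes") <- bayes
    attr(out, "labels") <- substrate_classes()
    out
  })
}

#' Observation sampler scheme
#'
#' Emulates a field sampling programme: points are drawn from marine cells
#' inside a depth window, with inclusion probability proportional to a
#' per-class bias multiplier (e.g. grab sampling favouring Rock) times an
#' optional shallow bias (weight halves every `depth_bias_scale` m).
#'
#' @param name One of `"grab"`, `"dive"`, `"camera"`, `"rov"` (or any label).
#' @param depth_min,depth_max Depth window (m); points fall in
#'   `(depth_min, depth_max]`.
#' @param bias Named numeric length-4 (Rock, Mixed, Sand, Mud) of positive
#'   relative inclusion rates.
#' @param n Number of points (> 0); cells may repeat.
#' @param jitter_sd Positional jitter sd (m); jittered positions are clipped
#'   to the sampled marine cell.
#' @param depth_bias_scale Depth (m) at which inclusion weight halves;
#'   `Inf` (default) means no depth bias within the window.
#' @param role `"build"` or `"independent"`.
#' @param seed Integer seed.
#' @return An object of class `sampler_scheme`.
#' @export
sampler_scheme <- function(name, depth_min, depth_max,
                           bias = c(Rock = 1, Mixed = 1, Sand = 1, Mud = 1),
                           n = 1000, jitter_sd = 5,
                           depth_bias_scale = Inf,
                           role = c("build", "independent"), seed = 1) {
  role <- match.arg(role)
  if (depth_min >= depth_max) stop("depth window must have min < max")
  if (n <= 0) stop("`n` must be > 0")
  bias <- bias[substrate_classes()]
  if (anyNA(bias) || any(bias <= 0))
    stop("`bias` must give a positive multiplier for each of ",
         paste(substrate_classes(), collapse = ", "))
  structure(list(name = name, depth_min = depth_min, depth_max = depth_max,
                 bias = bias, n = as.integer(n), jitter_sd = jitter_sd,
                 depth_bias_scale = depth_bias_scale, role = role,
                 seed = seed),
            class = "sampler_scheme")
}

#' Sample biased point observations from a truth grid
#'
#' Draws `scheme$n` points (cells with replacement) from marine cells whose
#' depth lies in the scheme's window, with inclusion probability
#' proportional to the class bias multiplier and the shallow bias. The
#' recorded class is the truth grid's class at the cell (so label noise in
#' the truth is the only observation error); the recorded depth is the
#' bathymetry at the cell. Deterministic given the scheme seed.
#'
#' @param truth Class grid from [simulate_truth()].
#' @param bathy The `depth_grid` the truth was generated on.
#' @param scheme A `sampler_scheme`.
#' @return A data.frame with columns `x, y, depth_m, class, source, role`
#'   (an observation table).
#' @export
sample_observations <- function(truth, bathy, scheme) {
  stopifnot(is_depth_grid(truth), is_depth_grid(bathy),
            inherits(scheme, "sampler_scheme"))
  if (!same_geometry(truth, bathy)) stop("truth and bathymetry differ in geometry")
  depth <- bathy$values
  cls <- truth$values
  eligible <- which(!is.na(cls) & depth > scheme$depth_min &
                      depth <= scheme$depth_max)
  if (!length(eligible))
    stop("empty eligible region: no marine cells in depth window (",
         scheme$depth_min, ", ", scheme$depth_max, "]")
  w <- scheme$bias[cls[eligible]]
  if (is.finite(scheme$depth_bias_scale))
    w <- w * 2^(-depth[eligible] / scheme$depth_bias_scale)
  with_seed(scheme$seed, {
    pick <- eligible[sample.int(length(eligible), scheme$n, replace = TRUE,
                                prob = w)]
    rc <- arrayInd(pick, dim(cls))
    ctr <- cell_xy(bathy, rc[, 1], rc[, 2])
    half <- bathy$cell / 2
    jx <- pmax(pmin(rnorm(scheme$n, 0, scheme$jitter_sd), half * 0.999),
               -half * 0.999)
    jy <- pmax(pmin(rnorm(scheme$n, 0, scheme$jitter_sd), half * 0.999),
               -half * 0.999)
    data.frame(
      x = ctr$x + jx, y = ctr$y + jy,
      depth_m = depth[pick],
      class = factor(substrate_classes()[cls[pick]],
                     levels = substrate_classes()),
      source = scheme$name, role = scheme$role,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a coarse-resolution energy field
#'
#' Stand-in for an ocean-model output (tidal speed or circulation): a
#' smooth, positive random field on its own coarse grid covering the extent
#' of a target bathymetry, to be resampled onto model grids with
#' [resample_energy()].
#'
#' @param bathy Target `depth_grid` whose extent the field must cover.
#' @param cell Native cell size of the energy field (m); must be coarser
#'   than the bathymetry.
#' @param mean_level,sd_level Mean and sd of the field (e.g. m/s).
#' @param seed Integer seed.
#' @return A `depth_grid` holding the energy values (sign convention not
#'   applied; values are the field itself).
#' @export
simulate_energy_field <- function(bathy, cell = 600, mean_level = 0.5,
                                  sd_level = 0.2, seed = 1) {
  stopifnot(is_depth_grid(bathy))
  if (cell <= bathy$cell) stop("energy field must be coarser than the bathymetry")
  ext_x <- ncol(bathy$values) * bathy$cell
  ext_y <- nrow(bathy$values) * bathy$cell
  nc <- max(2L, ceiling(ext_x / cell) + 1L)
  nr <- max(2L, ceiling(ext_y / cell) + 1L)
  with_seed(seed, {
    f <- mean_level + sd_level * gaussian_field(nr, nc, max(2, nr / 4))
    f <- pmax(f, 0)
    # centre the coarse grid on the target extent
    ox <- bathy$origin[1] - (nc * cell - ext_x) / 2
    oy <- bathy$origin[2] - (nr * cell - ext_y) / 2
    depth_grid(f, cell, c(ox, oy), bathy$crs)
  })
}
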