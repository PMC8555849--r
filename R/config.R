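#' Experiment configuration
#'
#' Assembles and validates the full configuration of a synthetic
#' classification experiment: generator parameters, sampler schemes for the
#' build and independent data, the two analysis resolutions, named
#' rectangular regions, weighting arms, forest settings and seeds.
#'
#' @param seafloor Named list of [seafloor_params()] arguments (without
#'   `cell` and `seed`, which the driver supplies).
#' @param truth Named list of [truth_params()] arguments (without `seed`).
#' @param energy Named list: `cell`, `mean_level`, `sd_level` of the coarse
#'   energy fields.
#' @param build_schemes,ide_schemes Lists of sampler definitions (named
#'   lists of [sampler_scheme()] arguments without `role`/`seed`).
#' @param resolutions Named list: `fine_cell` and `coarse_cell` (m); the
#'   coarse cell must be an integer multiple of the fine cell.
#' @param regions Named list of rectangles
#'   (`row_min,row_max,col_min,col_max`, in fine-grid cells), or `NULL` for
#'   a single region spanning the grid.
#' @param forest Named list: `n_trees`, `sample_fraction`.
#' @param arms Character subset of `c("prevalence", "none")`.
#' @param train_frac Training proportion of the build split.
#' @param screen_max_diff Depth-discrepancy screen for independent data (m).
#' @param min_stratum Minimum evaluable points for a reported stratum.
#' @param seeds Integer vector of run seeds (>= 1 entry, each < 2e6).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(
    seafloor = list(), truth = list(),
    energy = list(cell = 600, mean_level = 0.5, sd_level = 0.2),
    build_schemes = default_build_schemes(),
    ide_schemes = default_ide_schemes(),
    resolutions = list(fine_cell = 20, coarse_cell = 100),
    regions = NULL,
    forest = list(n_trees = 1000, sample_fraction = 0.6),
    arms = c("prevalence", "none"),
    train_frac = 0.67, screen_max_diff = 50, min_stratum = 30,
    seeds = 1L) {
  fine <- resolutions$fine_cell; coarse <- resolutions$coarse_cell
  if (is.null(fine) || is.null(coarse))
    stop("`resolutions` must give fine_cell and coarse_cell")
  if (coarse <= fine || coarse %% fine != 0)
    stop("coarse cell size must be an integer multiple of the fine cell size")
  if (!length(seeds)) stop("need at least one seed")
  if (any(seeds < 0 | seeds >= 2e6)) stop("seeds must lie in [0, 2e6)")
  if (!all(arms %in% c("prevalence", "none")) || !length(arms))
    stop("`arms` must be a non-empty subset of prevalence/none")
  # materialise defaults so saved configs are complete
  sf_def <- formals(seafloor_params)
  sf <- utils::modifyList(lapply(sf_def[setdiff(names(sf_def),
                                                c("cell", "seed"))], eval),
                          seafloor)
  tr_def <- formals(truth_params)
  tr <- utils::modifyList(lapply(tr_def[setdiff(names(tr_def), "seed")],
                                 eval), truth)
  if (is.null(regions))
    regions <- list(all = list(row_min = 1, row_max = sf$nr,
                               col_min = 1, col_max = sf$nc))
  if (!length(regions) || is.null(names(regions)))
    stop("`regions` must be a named list of rectangles")
  for (r in regions) {
    if (!all(c("row_min", "row_max", "col_min", "col_max") %in% names(r)))
      stop("each region needs row_min/row_max/col_min/col_max")
  }
  structure(list(
    synthetic = list(seafloor = sf, truth = tr, energy = energy,
                     build_schemes = build_schemes,
                     ide_schemes = ide_schemes),
    resolutions = list(fine_cell = fine, coarse_cell = coarse),
    regions = regions, forest = forest, arms = arms,
    train_frac = train_frac, screen_max_diff = screen_max_diff,
    min_stratum = min_stratum, seeds = as.integer(seeds)
  ), class = "experiment_config")
}

#' Default build sampler schemes
#'
#' A grab-style sampler biased shallow (inclusion weight halving every 40 m
#' of depth) and toward Rock (multiplier 2.5), plus an unbiased dive-style
#' sampler restricted to 0-20 m: the sampling structure of typical
#' hydrographic-survey build data.
#'
#' @return List of sampler definitions.
#' @export
default_build_schemes <- function() {
  list(
    list(name = "grab", depth_min = 0, depth_max = 1000,
         bias = list(Rock = 2.5, Mixed = 1, Sand = 1, Mud = 1),
         n = 3000, jitter_sd = 5, depth_bias_scale = 40),
    list(name = "dive", depth_min = 0, depth_max = 20,
         bias = list(Rock = 1, Mixed = 1, Sand = 1, Mud = 1),
         n = 800, jitter_sd = 5, depth_bias_scale = Inf)
  )
}

#' Default independent-evaluation sampler schemes
#'
#' Dive (0-19 m), drop camera (16-60 m) and ROV (deeper than 20 m) samplers
#' with unbiased class inclusion, mirroring the depth windows of typical
#' independent benthic survey programmes.
#'
#' @return List of sampler definitions.
#' @export
default_ide_schemes <- function() {
  list(
    list(name = "dive", depth_min = 0, depth_max = 19,
         bias = list(Rock = 1, Mixed = 1, Sand = 1, Mud = 1),
         n = 700, jitter_sd = 5, depth_bias_scale = Inf),
    list(name = "camera", depth_min = 16, depth_max = 60,
         bias = list(Rock = 1, Mixed = 1, Sand = 1, Mud = 1),
         n = 500, jitter_sd = 5, depth_bias_scale = Inf),
    list(name = "rov", depth_min = 20, depth_max = 1000,
         bias = list(Rock = 1, Mixed = 1, Sand = 1, Mud = 1),
         n = 700, jitter_sd = 5, depth_bias_scale = Inf)
  )
}

.config_keys <- c("synthetic", "resolutions", "regions", "forest", "arms",
                  "train_frac", "screen_max_diff", "min_stratum", "seeds")
.synth_keys <- c("seafloor", "truth", "energy", "build_schemes",
                 "ide_schemes")

#' Load an experiment configuration from YAML
#'
#' Reads, validates and default-fills a YAML experiment configuration.
#' Unknown keys are rejected with a field-level message.
#'
#' @param path Path to a YAML file.
#' @return A validated `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$synthetic)) {
    unknown <- setdiff(names(raw$synthetic), .synth_keys)
    if (length(unknown))
      stop("unknown synthetic key(s): ", paste(unknown, collapse = ", "))
  }
  args <- c(raw$synthetic[.synth_keys[.synth_keys %in% names(raw$synthetic)]],
            raw[setdiff(names(raw), "synthetic")])
  # YAML represents Inf as the string ".inf" in some emitters; normalise
  args <- rapply(args, function(v) {
    if (is.character(v) && length(v) == 1 && v %in% c(".inf", "Inf")) Inf
    else v
  }, how = "replace")
  do.call(experiment_config, args)
}

#' Save an experiment configuration to YAML
#'
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  out <- unclass(config)
  flat <- c(list(synthetic = out$synthetic),
            out[setdiff(names(out), "synthetic")])
  yaml::write_yaml(flat, path)
  invisible(path)
}
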