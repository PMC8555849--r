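scheme_from_cfg <- function(cfg, role, seed) {
  sampler_scheme(name = cfg$name, depth_min = cfg$depth_min,
                 depth_max = cfg$depth_max,
                 bias = unlist(cfg$bias), n = cfg$n,
                 jitter_sd = cfg$jitter_sd,
                 depth_bias_scale = cfg$depth_bias_scale,
                 role = role, seed = seed)
}

# metric rows for one (model, dataset) over "all" + depth-zone strata
eval_strata <- function(observed, predicted, depth, min_stratum,
                        labels = substrate_classes()) {
  strata <- c(list(all = seq_along(observed)),
              split(seq_along(observed), assign_zone(depth)))
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    n <- length(idx)
    if (n == 0) return(NULL)
    insufficient <- n < min_stratum && nm != "all"
    if (insufficient || length(unique(observed[idx])) < 1) {
      ms <- data.frame(n = n, imbalance = NA_real_, oa = NA_real_,
                       tss = NA_real_, tnr = NA_real_, quantity = NA_real_,
                       exchange = NA_real_, shift = NA_real_,
                       prev_l1 = NA_real_, oa_adj = NA_real_,
                       tnr_adj = NA_real_)
    } else {
      ms <- metric_set(observed[idx], predicted[idx], labels)
    }
    cbind(data.frame(stratum = nm, insufficient = insufficient), ms)
  })
  do.call(rbind, rows)
}

#' Evaluate a model's predictive power on prepared independent data
#'
#' Computes the full metric set for one model against an independent
#' observation table (already mode-aggregated and depth-screened), overall
#' and per depth zone. Accuracies adjusted to their no-information
#' baselines (`oa_adj`, `tnr_adj`; the TSS baseline is 0 so TSS is its own
#' adjusted value) are included. Strata with fewer than `min_stratum`
#' points are flagged `insufficient` rather than zero-filled.
#'
#' @param model A `substrate_model`.
#' @param independent Prepared independent observation table.
#' @param stack The `predictor_stack` matching the model.
#' @param min_stratum Minimum points for a reported stratum.
#' @return Data frame of metric rows (one per stratum).
#' @export
ide_evaluate <- function(model, independent, stack, min_stratum = 30) {
  joined <- join_predictors(independent, stack)
  if (nrow(joined) == 0) stop("no independent observations on valid cells")
  pred <- predict_points(model, joined)
  eval_strata(as.character(joined$class), as.character(pred),
              joined$depth_m, min_stratum)
}

#' Run the full synthetic classification experiment
#'
#' For each seed: simulates a shelf bathymetry and substrate truth at the
#' fine resolution; aggregates the bathymetry (block mean) to the coarse
#' resolution; derives predictor stacks at both resolutions (fetch at the
#' fine resolution only); samples biased build and independent
#' observations; splits the build data 67/33 (shared across arms and
#' resolutions); fits the coastwide (coarse) model and one fine model per
#' region, each with and without prevalence weighting; and evaluates model
#' fit on the shared test partition and predictive power on each
#' independent set, overall and per depth zone.
#'
#' A seed whose pipeline fails is logged and skipped; the run continues.
#'
#' @param config An `experiment_config`.
#' @param out_dir Optional output directory: tidy metric CSVs, first-seed
#'   class maps and a JSON run manifest are written there.
#' @return Data frame of metric rows (columns: seed, region, resolution,
#'   weighting, dataset, stratum, insufficient, n, metrics...), with
#'   attributes `failures` (named list of per-seed errors) and `manifest`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  results <- list()
  failures <- list()
  maps_written <- character(0)
  for (seed in config$seeds) {
    res <- tryCatch(run_seed(config, seed),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(seed)]] <- conditionMessage(res)
      next
    }
    results[[as.character(seed)]] <- res$metrics
    if (!is.null(out_dir) && !length(maps_written)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(res$maps)) {
        p <- file.path(out_dir, sprintf("map_seed%d_%s.tif", seed, nm))
        write_grid(res$maps[[nm]], p, kind = "class")
        maps_written <- c(maps_written, p, paste0(p, ".json"))
      }
    }
  }
  if (!length(results))
    stop("every seed failed; first error: ", failures[[1]])
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  manifest <- list(config_hash = object_hash(unclass(config)),
                   seeds = config$seeds,
                   version = as.character(utils::packageVersion("benthoscape")),
                   n_rows = nrow(out), failures = failures,
                   files = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "metrics.csv")
    write.csv(out, csv, row.names = FALSE)
    manifest$files <- c(csv, maps_written)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(out, "failures") <- failures
  attr(out, "manifest") <- manifest
  out
}

# One seeded pass of the pipeline; returns metric rows + first-seed maps.
run_seed <- function(config, seed) {
  base <- seed * 1000
  syn <- config$synthetic
  fine <- config$resolutions$fine_cell
  factor <- config$resolutions$coarse_cell / fine

  sp <- do.call(seafloor_params,
                c(syn$seafloor, list(cell = fine, seed = base + 1)))
  bathy_f <- simulate_bathymetry(sp)
  bathy_c <- block_aggregate(bathy_f, factor)

  tide <- do.call(simulate_energy_field,
                  c(list(bathy = bathy_f), syn$energy,
                    list(seed = base + 3)))
  circ <- do.call(simulate_energy_field,
                  c(list(bathy = bathy_f), syn$energy,
                    list(seed = base + 4)))

  stack_f <- build_stack(bathy_f, tide, circ, "regional")
  stack_c <- build_stack(bathy_c, tide, circ, "coastwide")

  tp <- do.call(truth_params, c(syn$truth, list(seed = base + 2)))
  energy_stack <- predictor_stack(
    list(fetch = stack_f$layers$fetch, tide = stack_f$layers$tide,
         slope = stack_f$layers$slope), bathy_f)
  truth <- simulate_truth(bathy_f, tp, energy_stack)

  build_obs <- do.call(rbind, lapply(seq_along(syn$build_schemes),
    function(i) sample_observations(truth, bathy_f,
      scheme_from_cfg(syn$build_schemes[[i]], "build", base + 10 + i))))
  build_obs$row_id <- seq_len(nrow(build_obs))

  parts <- split_build(build_obs, config$train_frac, seed = base + 5)
  train_f <- join_predictors(parts$train, stack_f)
  test_f <- join_predictors(parts$test, stack_f)
  train_c <- join_predictors(parts$train, stack_c)
  test_c <- join_predictors(parts$test, stack_c)

  in_region <- function(tab, rect, grid) {
    rc <- cell_at(grid, tab$x, tab$y)
    ok <- !is.na(rc$row) & rc$row >= rect$row_min & rc$row <= rect$row_max &
      rc$col >= rect$col_min & rc$col <= rect$col_max
    tab[ok, , drop = FALSE]
  }

  models <- list()
  for (arm in config$arms) {
    fs <- forest_spec(n_trees = config$forest$n_trees,
                      sample_fraction = config$forest$sample_fraction,
                      weighting = arm, seed = base + 6)
    models[[length(models) + 1]] <- list(
      region = "coastwide", resolution = "coarse", weighting = arm,
      model = fit_substrate(train_c, fs), stack = stack_c,
      test = test_c)
    for (rn in names(config$regions)) {
      rect <- config$regions[[rn]]
      tr <- in_region(train_f, rect, bathy_f)
      te <- in_region(test_f, rect, bathy_f)
      models[[length(models) + 1]] <- list(
        region = rn, resolution = "fine", weighting = arm,
        model = fit_substrate(tr, fs), stack = stack_f, test = te)
    }
  }

  ide_prepared <- lapply(seq_along(syn$ide_schemes), function(i) {
    raw <- sample_observations(truth, bathy_f,
      scheme_from_cfg(syn$ide_schemes[[i]], "independent", base + 20 + i))
    agg <- aggregate_mode(raw, bathy_f)
    screen_depth(agg, bathy_f, config$screen_max_diff)
  })
  names(ide_prepared) <- vapply(syn$ide_schemes, `[[`, "", "name")

  rows <- list()
  for (m in models) {
    # guard: fit metrics never use training rows
    stopifnot(!any(m$test$row_id %in%
                     (if (m$resolution == "fine") train_f else train_c)$row_id))
    pred <- predict_points(m$model, m$test)
    fit_rows <- eval_strata(as.character(m$test$class), as.character(pred),
                            m$test$depth_m, config$min_stratum)
    fit_rows$oob <- ifelse(fit_rows$stratum == "all", m$model$oob, NA_real_)
    fit_rows <- cbind(data.frame(seed = seed, region = m$region,
                                 resolution = m$resolution,
                                 weighting = m$weighting,
                                 dataset = "fit"), fit_rows)
    rows[[length(rows) + 1]] <- fit_rows
    for (ds in names(ide_prepared)) {
      ide <- ide_prepared[[ds]]
      if (nrow(ide) == 0) next
      ide_rows <- ide_evaluate(m$model, ide, m$stack, config$min_stratum)
      ide_rows$oob <- NA_real_
      ide_rows <- cbind(data.frame(seed = seed, region = m$region,
                                   resolution = m$resolution,
                                   weighting = m$weighting,
                                   dataset = ds), ide_rows)
      rows[[length(rows) + 1]] <- ide_rows
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  maps <- list(truth = truth)
  first <- models[[1]]
  maps[[paste0("pred_", first$resolution, "_", first$weighting)]] <-
    predict_grid(first$model, first$stack)
  list(metrics = metrics, maps = maps)
}

#' Weighted-minus-unweighted metric differences
#'
#' Pairs the prevalence-weighted and unweighted arms on (seed, region,
#' resolution, dataset, stratum) and reports, per metric, the weighted and
#' unweighted values and their difference (weighted minus unweighted).
#'
#' @param results Metric rows from [run_experiment()].
#' @param metrics Character vector of metric columns to compare.
#' @return Long data frame: one row per (pairing, metric).
#' @export
compare_weighting <- function(results,
                              metrics = c("oa", "tss", "tnr", "quantity",
                                          "exchange", "shift", "prev_l1")) {
  stopifnot(is.data.frame(results))
  arms <- unique(results$weighting)
  if (!all(c("prevalence", "none") %in% arms))
    stop("missing arm: need both 'prevalence' and 'none' results")
  keys <- c("seed", "region", "resolution", "dataset", "stratum")
  w <- results[results$weighting == "prevalence", , drop = FALSE]
  u <- results[results$weighting == "none", , drop = FALSE]
  kw <- do.call(paste, c(w[keys], sep = "\r"))
  ku <- do.call(paste, c(u[keys], sep = "\r"))
  common <- intersect(kw, ku)
  w <- w[match(common, kw), , drop = FALSE]
  u <- u[match(common, ku), , drop = FALSE]
  out <- do.call(rbind, lapply(metrics, function(mcol) {
    cbind(w[keys],
          data.frame(metric = mcol, weighted = w[[mcol]],
                     unweighted = u[[mcol]],
                     delta = w[[mcol]] - u[[mcol]]))
  }))
  rownames(out) <- NULL
  out
}
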