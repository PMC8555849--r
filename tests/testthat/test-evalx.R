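# Compact experiment configuration: 150 x 150 cells at 40 m (coarse 200 m)
# keeps every pipeline stage exercised at a fraction of the full cost.
tiny_config <- function(seeds = 1, arms = c("prevalence", "none"),
                        n_build = 1500) {
  experiment_config(
    seafloor = list(nr = 150, nc = 150),
    build_schemes = list(list(
      name = "grab", depth_min = 0, depth_max = 1000,
      bias = list(Rock = 2.5, Mixed = 1, Sand = 1, Mud = 1),
      n = n_build, jitter_sd = 5, depth_bias_scale = 40)),
    ide_schemes = list(list(
      name = "dive", depth_min = 0, depth_max = 19,
      bias = list(Rock = 1, Mixed = 1, Sand = 1, Mud = 1),
      n = 400, jitter_sd = 5, depth_bias_scale = Inf)),
    resolutions = list(fine_cell = 40, coarse_cell = 200),
    forest = list(n_trees = 50, sample_fraction = 0.6),
    arms = arms, min_stratum = 15, seeds = seeds)
}

test_that("configuration validation enforces the schema", {
  cfg <- experiment_config()
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$resolutions$coarse_cell %% cfg$resolutions$fine_cell, 0)
  expect_error(experiment_config(resolutions = list(fine_cell = 20,
                                                    coarse_cell = 70)),
               "integer multiple")
  expect_error(experiment_config(seeds = integer(0)), "seed")
  expect_error(experiment_config(arms = "both"), "arms")
})

test_that("YAML configs round-trip and reject unknown keys", {
  cfg <- tiny_config()
  p <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, p)
  cfg2 <- load_config(p)
  expect_equal(cfg2, cfg)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("train_frac: 0.5", "typo_key: 1"), bad)
  expect_error(load_config(bad), "typo_key")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synthetic:", "  bogus: 1"), bad2)
  expect_error(load_config(bad2), "bogus")
})

test_that("one experiment seed yields the expected model bookkeeping", {
  res <- run_experiment(tiny_config())
  all_rows <- res[res$stratum == "all" & res$dataset == "fit", ]
  # 2 weighting arms x (coastwide + 1 region) = 4 model rows minimum
  expect_gte(nrow(all_rows), 4)
  expect_setequal(unique(all_rows$weighting), c("prevalence", "none"))
  expect_setequal(unique(all_rows$resolution), c("coarse", "fine"))
  expect_true(all(is.finite(all_rows$oob)))
  expect_true(all(res$dataset %in% c("fit", "dive")))

  # the disagreement decomposition closes for every evaluated stratum
  ok <- !res$insufficient & !is.na(res$oa)
  expect_true(all(abs(res$quantity[ok] + res$exchange[ok] +
                        res$shift[ok] + res$oa[ok] - 1) < 1e-12))
})

test_that("the experiment pipeline is deterministic given config and seeds", {
  r1 <- run_experiment(tiny_config())
  r2 <- run_experiment(tiny_config())
  attributes(r1) <- attributes(r1)[c("names", "class", "row.names")]
  attributes(r2) <- attributes(r2)[c("names", "class", "row.names")]
  expect_identical(r1, r2)
})

test_that("experiment artifacts land on disk with a manifest", {
  dir <- withr::local_tempdir()
  res <- run_experiment(tiny_config(), out_dir = dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_rows, nrow(res))
  expect_true(all(file.exists(man$files)))
  expect_true(any(grepl("map_seed", man$files)))
})

test_that("weighting comparison pairs arms and degenerates to zero under no contrast", {
  res <- run_experiment(tiny_config())
  cmp <- compare_weighting(res)
  expect_true(all(c("metric", "weighted", "unweighted", "delta") %in%
                    names(cmp)))
  # one row per (stratum pairing, metric)
  keys <- paste(cmp$seed, cmp$region, cmp$resolution, cmp$dataset,
                cmp$stratum, cmp$metric)
  expect_false(any(duplicated(keys)))
  expect_equal(cmp$delta, cmp$weighted - cmp$unweighted)

  solo <- res[res$weighting == "prevalence", ]
  expect_error(compare_weighting(solo), "missing arm")
})

test_that("independent evaluation reports baseline-adjusted accuracies", {
  w <- small_world(1)
  obs <- sample_observations(w$truth, w$bathy,
                             sampler_scheme("grab", 0, 1000, n = 2000,
                                            seed = 41))
  m <- fit_substrate(join_predictors(obs, w$stack),
                     forest_spec(n_trees = 60, seed = 2))
  raw <- sample_observations(w$truth, w$bathy,
                             sampler_scheme("dive", 0, 19, n = 600,
                                            role = "independent", seed = 43))
  ide <- screen_depth(aggregate_mode(raw, w$bathy), w$bathy, 50)
  rows <- ide_evaluate(m, ide, w$stack, min_stratum = 15)
  all_row <- rows[rows$stratum == "all", ]
  expect_equal(all_row$tnr_adj, all_row$tnr - 0.75, tolerance = 1e-12)
  expect_equal(all_row$oa_adj, all_row$oa - 0.25, tolerance = 1e-12)
  expect_true(all(rows$insufficient[is.na(rows$oa)]))
})

test_that("a shared-context independent sampler matches fit skill; a biased one degrades it", {
  skills <- sapply(1:5, function(s) {
    w <- small_world(s)
    build <- sample_observations(w$truth, w$bathy,
      sampler_scheme("grab", 0, 1000,
                     bias = c(Rock = 2.5, Mixed = 1, Sand = 1, Mud = 1),
                     n = 3000, depth_bias_scale = 40, seed = s * 1000 + 51))
    joined <- join_predictors(build, w$stack)
    sp <- split_build(joined, 0.67, seed = s * 1000 + 52)
    m <- fit_substrate(sp$train, forest_spec(n_trees = 80,
                                             seed = s * 1000 + 53))
    fit_tss <- metric_set(sp$test$class, predict_points(m, sp$test))$tss
    # same sampling context as the build data
    same <- sample_observations(w$truth, w$bathy,
      sampler_scheme("grab2", 0, 1000,
                     bias = c(Rock = 2.5, Mixed = 1, Sand = 1, Mud = 1),
                     n = 1500, depth_bias_scale = 40,
                     role = "independent", seed = s * 1000 + 54))
    same_tss <- ide_evaluate(m, screen_depth(aggregate_mode(same, w$bathy),
                                             w$bathy, 50),
                             w$stack)$tss[1]
    # opposite class bias: Rock under-sampled 3x
    opp <- sample_observations(w$truth, w$bathy,
      sampler_scheme("opp", 0, 1000,
                     bias = c(Rock = 1 / 3, Mixed = 1, Sand = 1, Mud = 1),
                     n = 1500, role = "independent", seed = s * 1000 + 55))
    opp_tss <- ide_evaluate(m, screen_depth(aggregate_mode(opp, w$bathy),
                                            w$bathy, 50),
                            w$stack)$tss[1]
    c(fit = fit_tss, same = same_tss, opp = opp_tss)
  })
  # shared context: close to fit skill on average
  expect_lt(mean(abs(skills["same", ] - skills["fit", ])), 0.08)
  # context shift lowers measured skill in the majority of seeds
  expect_gte(sum(skills["opp", ] < skills["fit", ]), 3)
})

test_that("regional skill spread detects non-stationary truth processes", {
  # one model evaluated over two tiles: under a single truth process the
  # between-tile TSS gap is small; when the tiles obey different energy
  # regimes the gap widens
  gaps <- sapply(1:3, function(s) {
    w <- small_world(s)
    half <- ncol(w$bathy$values) %/% 2
    es <- predictor_stack(list(fetch = w$stack$layers$fetch,
                               tide = w$stack$layers$tide,
                               slope = w$stack$layers$slope), w$bathy)
    # non-stationary truth: west tile as configured, east tile with the
    # fetch/tide influence inverted
    t_a <- simulate_truth(w$bathy, truth_params(seed = s * 1000 + 2), es)
    t_b <- simulate_truth(w$bathy,
                          truth_params(w_fetch = -1, w_tide = -0.7,
                                       seed = s * 1000 + 2), es)
    spliced <- t_a
    spliced$values[, (half + 1):ncol(spliced$values)] <-
      t_b$values[, (half + 1):ncol(t_b$values)]

    tss_gap <- function(truth) {
      obs <- sample_observations(truth, w$bathy,
        sampler_scheme("grab", 0, 1000, n = 3000, seed = s * 1000 + 61))
      joined <- join_predictors(obs, w$stack)
      sp <- split_build(joined, 0.67, seed = s * 1000 + 62)
      m <- fit_substrate(sp$train, forest_spec(n_trees = 80,
                                               seed = s * 1000 + 63))
      te <- sp$test
      rc <- benthoscape:::cell_at(w$bathy, te$x, te$y)
      west <- rc$col <= half
      tw <- metric_set(te$class[west],
                       predict_points(m, te[west, ]))$tss
      tE <- metric_set(te$class[!west],
                       predict_points(m, te[!west, ]))$tss
      abs(tw - tE)
    }
    c(stationary = tss_gap(w$truth), shifted = tss_gap(spliced))
  })
  expect_gte(sum(gaps["shifted", ] > gaps["stationary", ]), 2)
})
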