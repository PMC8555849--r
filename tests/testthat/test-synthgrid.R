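test_that("bathymetry generation is deterministic and shaped like a shelf", {
  p <- seafloor_params(nr = 60, nc = 80, cell = 20, seed = 11)
  a <- simulate_bathymetry(p)
  b <- simulate_bathymetry(p)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_bathymetry(seafloor_params(nr = 60, nc = 80,
                                                  seed = 12))$values))

  # pure ramp: strictly non-decreasing along the seaward (column) axis
  flatp <- seafloor_params(nr = 30, nc = 50, ridge_amplitude = 0,
                           fine_amplitude = 0, seed = 1)
  ramp <- simulate_bathymetry(flatp)
  expect_true(all(apply(ramp$values, 1, function(r) all(diff(r) >= 0))))

  expect_error(seafloor_params(nr = 8, nc = 8), "degenerate")
})

test_that("realised land fraction tracks the target across seeds", {
  hits <- 0
  for (s in 1:50) {
    b <- simulate_bathymetry(seafloor_params(seed = s))
    lf <- mean(b$values <= 0)
    if (abs(lf - 0.15) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("truth generation thresholds the latent index deterministically", {
  w <- truth_only(3)
  tr2 <- simulate_truth(w$bathy, truth_params(seed = 3002),
                        predictor_stack(list(
                          fetch = fetch_sum(w$bathy)$values,
                          tide = resample_energy(
                            simulate_energy_field(w$bathy, seed = 3003),
                            w$bathy)$values,
                          slope = derive_local(w$bathy, "slope")$values),
                          w$bathy))
  expect_true(all(tr2$values[marine_mask(w$bathy)] %in% 1:4))
  expect_true(all(is.na(tr2$values[!marine_mask(w$bathy)])))

  # determinism with zero noise
  tp0 <- truth_params(noise_sd = 0, label_noise = 0, seed = 5)
  es <- predictor_stack(list(fetch = fetch_sum(w$bathy)$values,
                             tide = w$bathy$values * 0 + 1,
                             slope = derive_local(w$bathy, "slope")$values),
                        w$bathy)
  t1 <- simulate_truth(w$bathy, tp0, es)
  t2 <- simulate_truth(w$bathy, tp0, es)
  expect_identical(t1$values, t2$values)

  # thresholds above the attainable index: everything is Mud
  hi <- truth_params(thresholds = c(50, 60, 70), noise_sd = 0,
                     label_noise = 0, seed = 5)
  th <- simulate_truth(w$bathy, hi, es)
  expect_true(all(th$values[marine_mask(w$bathy)] == 4L))

  expect_error(truth_params(thresholds = c(1, 1, 2)), "increasing")
  expect_error(simulate_truth(w$bathy, tp0,
                              predictor_stack(list(tide = es$layers$tide),
                                              w$bathy)),
               "missing energy layer")
})

test_that("class prevalences stay in a plausible band across seeds", {
  for (s in 1:20) {
    w <- truth_only(s)
    prev <- table(factor(w$truth$values[marine_mask(w$bathy)],
                         levels = 1:4))
    prev <- as.numeric(prev) / sum(prev)
    expect_true(all(prev >= 0.05 & prev <= 0.60),
                info = sprintf("seed %d: %s", s,
                               paste(round(prev, 3), collapse = " ")))
  }
})

test_that("samplers honour the depth window and are deterministic", {
  w <- small_world(1)
  sch <- sampler_scheme("dive", 0, 20, n = 500, seed = 9)
  o1 <- sample_observations(w$truth, w$bathy, sch)
  o2 <- sample_observations(w$truth, w$bathy, sch)
  expect_identical(o1, o2)
  expect_true(all(o1$depth_m > 0 & o1$depth_m <= 20))
  expect_equal(nrow(o1), 500)
  expect_equal(unique(o1$source), "dive")

  expect_error(sample_observations(w$truth, w$bathy,
                                   sampler_scheme("x", 5000, 6000, n = 10)),
               "empty eligible region")
  expect_error(sampler_scheme("x", 10, 5), "min < max")
})

test_that("unbiased sampling recovers map prevalence within a 99% CI", {
  w <- small_world(1)
  n <- 20000
  o <- sample_observations(w$truth, w$bathy,
                           sampler_scheme("grab", 0, 1000, n = n, seed = 4))
  win <- marine_mask(w$bathy) & w$bathy$values > 0 & w$bathy$values <= 1000
  map_prev <- as.numeric(table(factor(w$truth$values[win], levels = 1:4)))
  map_prev <- map_prev / sum(map_prev)
  samp_prev <- as.numeric(table(o$class)) / n
  z <- qnorm(0.995)
  for (k in 1:4) {
    half <- z * sqrt(map_prev[k] * (1 - map_prev[k]) / n)
    expect_lt(abs(samp_prev[k] - map_prev[k]), half + 0.01)
  }
})

test_that("class bias multipliers act as inclusion weights and are recoverable", {
  w <- small_world(1)
  n <- 50000
  # Rock multiplier 2: expected Rock share 2 p_R / (1 + p_R)
  o <- sample_observations(w$truth, w$bathy,
    sampler_scheme("grab", 0, 1000,
                   bias = c(Rock = 2, Mixed = 1, Sand = 1, Mud = 1),
                   n = n, seed = 8))
  win <- marine_mask(w$bathy)
  map_prev <- as.numeric(table(factor(w$truth$values[win], levels = 1:4)))
  map_prev <- map_prev / sum(map_prev)
  expected_rock <- 2 * map_prev[1] / (1 + map_prev[1])
  rock_share <- mean(o$class == "Rock")
  expect_lt(abs(rock_share - expected_rock),
            qnorm(0.995) * sqrt(expected_rock * (1 - expected_rock) / n) +
              0.01)

  # full multiplier recovery from sample vs map prevalence, within 10%
  bias <- c(Rock = 2, Mixed = 0.5, Sand = 1, Mud = 1.5)
  ob <- sample_observations(w$truth, w$bathy,
    sampler_scheme("grab", 0, 1000, bias = bias, n = n, seed = 12))
  samp_prev <- as.numeric(table(ob$class)) / n
  bhat <- samp_prev / map_prev
  bhat <- bhat / bhat[3]  # normalise to the Sand multiplier
  expect_true(all(abs(bhat - bias) / bias < 0.10))
})

test_that("truth patchiness decays with depth zone", {
  # distinct classes in 5x5 windows, averaged per zone band, must fall
  # 0-5 m -> 20-50 m -> 100-200 m for every seed
  diversity <- function(truth, bathy, dmin, dmax) {
    v <- truth$values
    idx <- which(bathy$values > dmin & bathy$values <= dmax & !is.na(v),
                 arr.ind = TRUE)
    idx <- idx[idx[, 1] > 2 & idx[, 1] < nrow(v) - 2 &
                 idx[, 2] > 2 & idx[, 2] < ncol(v) - 2, , drop = FALSE]
    if (nrow(idx) > 400) idx <- idx[seq(1, nrow(idx), length.out = 400), ]
    mean(apply(idx, 1, function(rc) {
      win <- v[(rc[1] - 2):(rc[1] + 2), (rc[2] - 2):(rc[2] + 2)]
      length(unique(win[!is.na(win)]))
    }))
  }
  for (s in 1:10) {
    w <- truth_only(s)
    d1 <- diversity(w$truth, w$bathy, 0, 5)
    d2 <- diversity(w$truth, w$bathy, 20, 50)
    d3 <- diversity(w$truth, w$bathy, 100, 200)
    expect_true(d1 > d2 && d2 > d3,
                info = sprintf("seed %d: %.2f %.2f %.2f", s, d1, d2, d3))
  }
})

test_that("energy fields are coarse, positive and cover the target extent", {
  b <- simulate_bathymetry(seafloor_params(nr = 60, nc = 60, seed = 2))
  e <- simulate_energy_field(b, cell = 300, seed = 5)
  expect_gt(e$cell, b$cell)
  expect_true(all(e$values >= 0))
  r <- resample_energy(e, b)
  expect_true(same_geometry(r, b))
  expect_error(simulate_energy_field(b, cell = 10), "coarser")
})
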