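# Shared fixtures, built in code. Worlds are memoised per session so the
# generator runs once per (seed, size) combination.

.world_cache <- new.env(parent = emptyenv())

# A compact synthetic world: bathymetry, energy fields, fine/coarse stacks
# and substrate truth. 150 x 150 cells at 40 m keeps every depth zone
# populated while staying fast.
small_world <- function(seed = 1, nr = 150, nc = 150, cell = 40) {
  key <- sprintf("w_%d_%d_%d_%g", seed, nr, nc, cell)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  base <- seed * 1000
  bathy <- simulate_bathymetry(
    seafloor_params(nr = nr, nc = nc, cell = cell, seed = base + 1))
  tide <- simulate_energy_field(bathy, seed = base + 3)
  circ <- simulate_energy_field(bathy, seed = base + 4)
  stack_f <- build_stack(bathy, tide, circ, "regional")
  truth <- simulate_truth(
    bathy, truth_params(seed = base + 2),
    predictor_stack(list(fetch = stack_f$layers$fetch,
                         tide = stack_f$layers$tide,
                         slope = stack_f$layers$slope), bathy))
  w <- list(bathy = bathy, tide = tide, circ = circ, stack = stack_f,
            truth = truth)
  .world_cache[[key]] <- w
  w
}

# Truth inputs only (no full stack): for prevalence / heterogeneity sweeps.
truth_only <- function(seed, nr = 150, nc = 150, cell = 40) {
  base <- seed * 1000
  bathy <- simulate_bathymetry(
    seafloor_params(nr = nr, nc = nc, cell = cell, seed = base + 1))
  tide <- simulate_energy_field(bathy, seed = base + 3)
  marine <- marine_mask(bathy)
  msk <- function(m) { m[!marine] <- NA_real_; m }
  energy <- predictor_stack(list(
    fetch = msk(fetch_sum(bathy)$values),
    tide = msk(resample_energy(tide, bathy)$values),
    slope = msk(derive_local(bathy, "slope")$values)), bathy)
  list(bathy = bathy,
       truth = simulate_truth(bathy, truth_params(seed = base + 2), energy))
}

# Perfectly separable 4-class table: class = sign pattern of 2 predictors.
separable_table <- function(n = 400, seed = 1) {
  set.seed(seed)
  u <- runif(n, -1, 1); v <- runif(n, -1, 1)
  cls <- ifelse(u > 0, ifelse(v > 0, "Rock", "Mixed"),
                ifelse(v > 0, "Sand", "Mud"))
  data.frame(u = u, v = v,
             class = factor(cls, levels = substrate_classes()))
}

# Plain observation table on a grid, for obsprep unit tests.
obs_table <- function(x, y, depth, cls, source = "test", role = "build") {
  data.frame(x = x, y = y, depth_m = depth,
             class = factor(cls, levels = substrate_classes()),
             source = source, role = role, stringsAsFactors = FALSE)
}

random_cm <- function(k = 4) {
  matrix(rpois(k * k, lambda = 8) + rbinom(k * k, 1, 0.5), k, k,
         dimnames = list(predicted = substrate_classes()[1:k],
                         observed = substrate_classes()[1:k]))
}
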