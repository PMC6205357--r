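# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small cohort on a 16^3 grid for fast unit tests.
tiny_scenario <- function(n = 24, seed = 7,
                          deficits = list(score = list(w_size = 0, w_focal = 1,
                                                       noise_sd = 1,
                                                       region = "focal"))) {
  scenario_config(
    n = n, dims = c(16, 16, 16), seed = seed,
    territory = list(center = c(6, 8, 8), scale = c(3.5, 4, 3.5), cutoff = 2),
    size_cc = list(meanlog = log(0.4), sdlog = 0.5, min = 0.05, max = 1.2),
    regions = list(focal = list(size = 10, offset = c(0, 0, 0))),
    deficits = deficits)
}

tiny_sim <- function(n = 24, seed = 7) {
  cached(sprintf("tiny-%d-%d", n, seed), simulate_cohort(tiny_scenario(n, seed)))
}

# Full desk-scale focal cohort (the default study conditions).
focal_sim <- function(seed = 1) {
  cached(sprintf("focal-%d", seed), simulate_cohort(scenario_focal(seed = seed)))
}

battery_sim <- function(seed = 11) {
  cached(sprintf("battery-%d", seed), simulate_cohort(scenario_battery(seed = seed)))
}

# A deterministic hand-built cohort: masks given as explicit voxel sets.
manual_cohort <- function(masks, dims = c(6, 6, 6), voxel_size = c(2, 2, 2)) {
  lesion_cohort(volume_geometry(dims, voxel_size), masks)
}
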