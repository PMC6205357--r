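test_that("territory field is a truncated Gaussian with connected support", {
  g <- volume_geometry(c(16, 16, 16))
  terr <- make_territory(g, center = c(6, 8, 8), scale = c(3, 4, 3), cutoff = 2)
  expect_equal(which.max(terr$prob), 6 + 16 * (8 - 1) + 256 * (8 - 1))
  expect_true(all(terr$prob >= 0 & terr$prob <= 1))
  expect_error(make_territory(g, scale = c(0, 0, 0)), "empty support")
})

test_that("planted regions are compact and inside the support", {
  terr <- make_territory(volume_geometry(c(16, 16, 16)),
                         center = c(6, 8, 8), scale = c(3, 4, 3), cutoff = 2)
  reg <- plant_critical_region(terr, 12)
  expect_length(reg, 12)
  expect_true(all(reg %in% terr$support))
  expect_error(plant_critical_region(terr, length(terr$support) + 1),
               "exceeds")
})

test_that("lesion growth hits the target exactly, stays 26-connected", {
  terr <- make_territory(volume_geometry(c(16, 16, 16)),
                         center = c(6, 8, 8), scale = c(3, 4, 3), cutoff = 2)
  expect_length(simulate_lesion(terr, 1, seed = 3), 1)

  les <- simulate_lesion(terr, 200, seed = 3)
  expect_length(les, 200)
  expect_true(all(les %in% terr$support))
  # 26-connectivity: every voxel beyond the first touches another one
  co <- arrayInd(les, terr$geometry$dims)
  d <- as.matrix(dist(co, method = "maximum"))
  diag(d) <- Inf
  expect_true(all(apply(d, 1, min) <= 1))

  # determinism and saturation
  expect_identical(simulate_lesion(terr, 200, seed = 3), les)
  full <- simulate_lesion(terr, length(terr$support), seed = 5)
  expect_identical(full, sort(terr$support))
  expect_error(simulate_lesion(terr, length(terr$support) + 1), "exhausted")
})

test_that("simulated cohorts respect size bounds and reproduce bit-identically", {
  sim <- tiny_sim()
  cfg <- tiny_scenario()
  sizes_vox <- lengths(sim$cohort$masks)
  vv <- 0.008
  expect_true(all(sizes_vox * vv >= cfg$size_cc$min - vv))
  expect_true(all(sizes_vox * vv <= cfg$size_cc$max + vv))

  sim2 <- simulate_cohort(tiny_scenario())
  expect_identical(sim$cohort$masks, sim2$cohort$masks)
  expect_identical(sim$cohort$behavior, sim2$cohort$behavior)

  expect_error(simulate_cohort(tiny_scenario(n = 0)), "n must be")
})

test_that("a cohort calibrated to chronic-stroke volumes spans 5.38-376.12 cc", {
  cfg <- scenario_config(n = 64, dims = c(32, 32, 32), voxel_size = c(4, 4, 4),
                         size_scale = 1, seed = 2,
                         regions = list(), deficits = list())
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$sizes_cc >= 5.38 - 0.064))
  expect_true(all(sim$cohort$sizes_cc <= 376.12 + 0.064))
  expect_gt(max(sim$cohort$sizes_cc), 100)  # heavy lognormal tail is present
})

test_that("deficit generator is exact in its noiseless limits", {
  sim <- tiny_sim()
  co <- sim$cohort
  reg <- sim$truth$regions$focal

  s_size <- generate_deficits(co, list(w_size = 1, w_focal = 0, noise_sd = 0))
  expect_equal(cor(s_size, co$sizes_cc, method = "spearman"), -1)
  expect_equal(cor(s_size, co$sizes_cc), -1)

  s_focal <- generate_deficits(co, list(w_size = 0, w_focal = 1, noise_sd = 0,
                                        critical_region = reg))
  load <- sim$truth$region_loads[, "focal"]
  expect_equal(abs(cor(s_focal, load)), 1)
})

test_that("size-only deficits reach the closed-form R2 of 0.5 at n = 500", {
  # w = 1, sigma = 1: R2 = w^2 / (w^2 + sigma^2) = 0.5
  cfg <- tiny_scenario(n = 500, seed = 42,
                       deficits = list(score = list(w_size = 1, w_focal = 0,
                                                    noise_sd = 1)))
  sim <- simulate_cohort(cfg)
  fit <- lm(score ~ sizes_cc, data = cbind(sim$cohort$behavior,
                                           sizes_cc = sim$cohort$sizes_cc))
  expect_lt(abs(summary(fit)$r.squared - 0.5), 0.1)
})

test_that("battery generator matches its factor model", {
  sim <- battery_sim()
  spec <- sim$truth$battery

  # planted latents: unit covariance after orthogonalization
  Fm <- sim$truth$latent_factors
  expect_equal(crossprod(scale(Fm, scale = FALSE)) / (nrow(Fm) - 1),
               diag(3), ignore_attr = TRUE, tolerance = 1e-8)

  # zero uniqueness: sample covariance has rank <= n_factors
  bat0 <- generate_battery(sim$truth$region_loads,
                           utils::modifyList(spec, list(uniqueness_sd = 0)),
                           seed = 5)
  ev <- eigen(cov(bat0$measures), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[4] / ev[1], 1e-10)

  # determinism
  bat1 <- generate_battery(sim$truth$region_loads, spec, seed = 9)
  bat2 <- generate_battery(sim$truth$region_loads, spec, seed = 9)
  expect_identical(bat1, bat2)
})

test_that("battery covariance converges to Lambda Lambda' + Psi", {
  resid_at <- function(n, seed) {
    cfg <- tiny_scenario(n = n, seed = seed, deficits = list())
    cfg$regions <- list(r1 = list(size = 12, offset = c(0, -3, 0)),
                        r2 = list(size = 12, offset = c(0, 3, 0)),
                        r3 = list(size = 12, offset = c(0, 0, 3)))
    cfg$battery <- list(loadings = default_loadings(17, 3),
                        uniqueness_sd = 0.53,
                        factor_regions = c("r1", "r2", "r3"),
                        orthogonalize = TRUE)
    sim <- simulate_cohort(cfg)
    L <- cfg$battery$loadings
    implied <- L %*% t(L)          # latents have unit covariance
    S <- cov(as.matrix(sim$cohort$behavior))
    off <- upper.tri(S)
    mean(abs(S[off] - implied[off]))
  }
  r100 <- resid_at(100, 31)
  r1000 <- resid_at(1000, 31)
  expect_lt(r1000, r100)          # residual shrinks with n
  expect_lt(r1000, 0.05)
})

test_that("simulated cohorts pass cohort validation round trip", {
  sim <- tiny_sim()
  co <- sim$cohort
  rebuilt <- lesion_cohort(co$geometry, co$masks, ids = co$ids,
                           behavior = co$behavior)
  expect_identical(rebuilt$sizes_cc, co$sizes_cc)
})
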