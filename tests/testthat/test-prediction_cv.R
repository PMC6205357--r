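test_that("folds are balanced, exhaustive and reproducible", {
  f <- assign_folds(128, 8, seed = 1)
  expect_equal(as.numeric(table(f)), rep(16, 8))
  expect_length(f, 128)

  f2 <- assign_folds(10, 3, seed = 2)
  expect_equal(sort(as.numeric(table(f2)), decreasing = TRUE), c(4, 3, 3))

  expect_identical(assign_folds(50, 5, seed = 9), assign_folds(50, 5, seed = 9))
  expect_error(assign_folds(4, 8), "k <= n")
})

test_that("template lesion load is the exact overlap fraction", {
  tmpl <- list(voxels = 1:200)
  expect_equal(template_lesion_load(1:500, tmpl), 1.0)     # lesion covers it
  expect_equal(template_lesion_load(300:400, tmpl), 0)     # disjoint
  expect_equal(template_lesion_load(c(1:50, 900:1000), tmpl), 0.25)
  expect_warning(l0 <- template_lesion_load(1:10, list(voxels = integer(0))),
                 "empty template")
  expect_equal(l0, 0)

  # monotone under lesion growth
  base <- c(1:30, 500:520)
  grown <- c(base, 31:60)
  expect_gte(template_lesion_load(grown, tmpl),
             template_lesion_load(base, tmpl))
})

test_that("nested regression matches a projection-matrix oracle", {
  # 10-point hand-constructed dataset
  size <- c(10, 25, 32, 47, 55, 61, 78, 84, 90, 99)
  load <- c(0.05, 0.30, 0.10, 0.55, 0.22, 0.70, 0.45, 0.95, 0.60, 0.81)
  score <- c(2.1, 1.4, 1.9, 0.3, 1.1, -0.2, 0.6, -1.5, 0.1, -0.9)
  cmp <- compare_models(score, size, load)

  zs <- (size - mean(size)) / sd(size)
  zl <- (load - mean(load)) / sd(load)
  rss <- function(A) {
    H <- A %*% solve(crossprod(A), t(A))
    sum(((diag(10) - H) %*% score)^2)
  }
  n <- 10
  tss <- sum((score - mean(score))^2)
  r0 <- rss(cbind(1, zs)); r1 <- rss(cbind(1, zs, zl))
  f_oracle <- ((r0 - r1) / 1) / (r1 / (n - 3))
  expect_equal(cmp$r2_size, 1 - r0 / tss, tolerance = 1e-10)
  expect_equal(cmp$r2_both, 1 - r1 / tss, tolerance = 1e-10)
  expect_equal(cmp$f_stat, f_oracle, tolerance = 1e-10)

  # partial r via explicit residual projections
  Hs <- cbind(1, zs) %*% solve(crossprod(cbind(1, zs)), t(cbind(1, zs)))
  rs <- score - Hs %*% score
  rl <- zl - Hs %*% zl
  expect_equal(cmp$partial_r,
               sum(rs * rl) / sqrt(sum(rs^2) * sum(rl^2)),
               tolerance = 1e-10)
  expect_equal(cmp$p_value, pf(f_oracle, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("redundant and orthogonal predictors hit their exact limits", {
  size <- seq(10, 100, length.out = 12)
  noise <- rnorm(12)

  # load identical to size: no added value
  r <- suppressWarnings(compare_models(size + noise, size, size / 100))
  expect_equal(r$delta_r2, 0, tolerance = 1e-10)
  expect_equal(r$partial_r, 0, tolerance = 1e-8)

  # load orthogonal to size and score = load exactly
  set.seed(2)
  load <- resid(lm(rnorm(12) ~ size))
  cmp <- suppressWarnings(compare_models(load, size, load))  # perfect fit
  expect_equal(cmp$r2_size, 0, tolerance = 1e-10)
  expect_equal(cmp$delta_r2, 1, tolerance = 1e-10)
  expect_equal(cmp$partial_r, 1, tolerance = 1e-10)

  # constant predictor is flagged, not fatal
  expect_warning(d <- compare_models(size + noise, size, rep(0.5, 12)),
                 "degenerate")
  expect_equal(d$r2_load, 0)
  expect_equal(d$delta_r2, 0)

  # nesting property on random data
  for (i in 1:10) {
    set.seed(i)
    cmpi <- compare_models(rnorm(20), runif(20, 1, 50), runif(20))
    expect_gte(cmpi$r2_both, cmpi$r2_size - 1e-10)
    expect_gte(cmpi$delta_r2, -1e-10)
  }
})

test_that("behavior-side residual control removes exactly the size component", {
  size <- runif(30, 5, 100)
  # orthogonal score: residuals equal the centered score
  set.seed(5)
  sc_orth <- resid(lm(rnorm(30) ~ size))
  expect_equal(behavior_residual_control(sc_orth, size),
               as.numeric(sc_orth - mean(sc_orth)), tolerance = 1e-10)
  # pure size function: residuals vanish
  expect_lt(max(abs(behavior_residual_control(3 - 0.5 * size, size))), 1e-10)
  # always uncorrelated with size, mean zero
  r <- behavior_residual_control(rnorm(30) + 0.05 * size, size)
  expect_lt(abs(mean(r)), 1e-12)
  expect_lt(abs(cor(r, size)), 1e-10)
})

test_that("cross-validated loads never leak the held-out participants", {
  sim <- tiny_sim()
  co <- sim$cohort
  y <- co$behavior$score
  folds <- assign_folds(length(co$masks), 3, seed = 4)
  params <- list(B = 150, v = 100, alpha = 0.05, seed = 11)

  pt <- cross_validated_loads(co, list(score = y), "vlsm", folds, params)
  expect_true(all(pt$loads >= 0 & pt$loads <= 1))
  expect_false(anyNA(pt$loads))

  # corrupt one held-out participant's score: its fold's templates must be
  # bit-identical (that participant is never in its own training set)
  victim <- which(folds == 2)[1]
  y2 <- y; y2[victim] <- 1e3
  pt2 <- cross_validated_loads(co, list(score = y2), "vlsm", folds, params)
  expect_identical(pt$templates[[2]]$score$voxels,
                   pt2$templates[[2]]$score$voxels)
  expect_equal(pt$loads[victim, ], pt2$loads[victim, ])

  # sccan route produces loads from the fixed-sparseness supports
  pts <- cross_validated_loads(co, list(score = y), "sccan", folds,
                               list(s = c(score = 0.1)))
  expect_true(all(pts$loads >= 0 & pts$loads <= 1))
  expect_equal(dim(pts$template_sizes), c(3, 1))
})

test_that("study pipeline dissociates focal from size-driven deficits", {
  focal <- focal_sim(seed = 31)
  res_f <- run_study2(focal$cohort, focal$cohort$behavior["score"],
                      methods = "vlsm", config = list(B = 300, seed = 31))
  cmp_f <- res_f$comparisons
  expect_lt(cmp_f$p_value, 0.05)
  expect_gt(cmp_f$delta_r2, 0)

  size_sim <- cached("size-128-32",
                     simulate_cohort(scenario_size_driven(seed = 32)))
  res_s <- run_study2(size_sim$cohort, size_sim$cohort$behavior["score"],
                      methods = "vlsm", config = list(B = 300, seed = 32))
  cmp_s <- res_s$comparisons
  expect_gt(cmp_s$r2_size, 0.3)          # size explains the deficit
  expect_lt(cmp_s$delta_r2, cmp_f$delta_r2)

  # structural invariants of the result table
  expect_true(all(cmp_f$r2_both >= cmp_f$r2_size - 1e-10))
  expect_named(res_f$predictors, "vlsm")
})

test_that("deficits with no variance yield empty templates and zero loads", {
  sim <- tiny_sim()
  co <- sim$cohort
  folds <- assign_folds(length(co$masks), 3, seed = 1)
  flat <- rep(1.7, length(co$masks))
  pt <- suppressWarnings(suppressMessages(
    cross_validated_loads(co, list(flat = flat), "vlsm", folds,
                          list(B = 150, seed = 2))))
  expect_true(all(pt$template_sizes == 0))
  expect_true(all(pt$loads == 0))
})
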