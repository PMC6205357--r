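# Impose an exact sample CORRELATION spectrum on random data: rotate the
# spectrum through a normalized Hadamard basis (unit diagonal exactly when
# the eigenvalues sum to the number of measures), then give whitened scores
# that covariance.
data_with_corr_eigenvalues <- function(n, eig, seed) {
  m <- length(eig)
  stopifnot(abs(sum(eig) - m) < 1e-12, log2(m) %% 1 == 0)
  H <- matrix(1)
  while (ncol(H) < m) H <- rbind(cbind(H, H), cbind(H, -H))
  V <- H / sqrt(m)
  C <- V %*% diag(eig) %*% t(V)
  set.seed(seed)
  X <- scale(matrix(rnorm(n * m), n), scale = FALSE)
  sv <- svd(X)
  Z <- sqrt(n - 1) * sv$u                      # exact identity covariance
  e <- eigen(C, symmetric = TRUE)
  Z %*% (e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors))
}

test_that("kaiser retention keeps eigenvalues > 1 and drops 0.915", {
  eig <- c(5, 4, 3, 0.915)
  eig <- c(eig, rep((16 - sum(eig)) / 12, 12))  # pad to trace 16
  B <- data_with_corr_eigenvalues(128, eig, seed = 1)
  fm <- fit_pca_varimax(B, "kaiser")
  expect_equal(fm$n_factors, 3)
  expect_equal(sort(fm$eigenvalues, decreasing = TRUE)[4], 0.915,
               tolerance = 1e-6)
})

test_that("varimax is a fixed point on perfect simple structure", {
  # 6 measures, 2 orthogonal factors, loadings already simple
  set.seed(4)
  F2 <- matrix(rnorm(2000 * 2), 2000)
  L <- rbind(matrix(c(0.9, 0), 3, 2, byrow = TRUE),
             matrix(c(0, 0.8), 4, 2, byrow = TRUE))
  B <- F2 %*% t(L) + 0.2 * matrix(rnorm(2000 * 7), 2000)
  fm <- fit_pca_varimax(B, 2)
  cong <- tucker_congruence(fm$loadings, L)
  expect_true(all(cong >= 0.98))
  # rotation matrix close to a signed permutation
  R <- abs(fm$rotation)
  expect_true(all(abs(sort(as.numeric(R), decreasing = TRUE)[1:2] - 1) < 0.2))
})

test_that("factor model satisfies its algebraic invariants", {
  sim <- battery_sim()
  fm <- fit_pca_varimax(sim$cohort$behavior, "kaiser")

  # orthonormal rotation
  expect_equal(crossprod(fm$rotation), diag(fm$n_factors),
               tolerance = 1e-8, ignore_attr = TRUE)

  # varimax preserves per-measure communalities
  k <- fm$n_factors
  e <- eigen(cor(as.matrix(sim$cohort$behavior)), symmetric = TRUE)
  A <- e$vectors[, 1:k] %*% diag(sqrt(e$values[1:k]))
  expect_equal(rowSums(fm$loadings^2), rowSums(A^2),
               tolerance = 1e-8, ignore_attr = TRUE)

  # total retained variance is rotation-invariant and matches eigenvalues
  expect_equal(sum(fm$variance_explained),
               sum(sort(fm$eigenvalues, decreasing = TRUE)[1:k]) /
                 length(fm$measures),
               tolerance = 1e-8)

  # scores are centered per factor
  expect_true(all(abs(colMeans(fm$scores)) < 1e-10))
})

test_that("planted 3-factor battery is recovered at n = 128", {
  sim <- battery_sim()
  fm <- fit_pca_varimax(sim$cohort$behavior, "kaiser")
  expect_equal(fm$n_factors, 3)
  cong <- tucker_congruence(fm$loadings, sim$truth$battery$loadings)
  expect_true(all(cong >= 0.95))

  # factor scores track the planted latents (aligned by the same permutation)
  sc <- factor_scores(fm, sim$cohort$behavior)
  perm <- attr(cong, "perm")
  r <- vapply(1:3, function(j) abs(cor(sc[, perm[j]],
                                       sim$truth$latent_factors[, j])), 1)
  expect_true(all(r >= 0.9))
})

test_that("noiseless planted battery yields near-perfect factor scores", {
  sim <- battery_sim()
  spec <- utils::modifyList(sim$truth$battery, list(uniqueness_sd = 1e-4))
  bat <- generate_battery(sim$truth$region_loads, spec, seed = 3)
  fm <- fit_pca_varimax(bat$measures, 3)
  sc <- factor_scores(fm, bat$measures)
  cong <- tucker_congruence(fm$loadings, spec$loadings)
  perm <- attr(cong, "perm")
  r <- vapply(1:3, function(j) abs(cor(sc[, perm[j]], bat$latents[, j])), 1)
  expect_true(all(r >= 0.99))
})

test_that("factor scores are a row-wise map of the battery", {
  sim <- battery_sim()
  fm <- fit_pca_varimax(sim$cohort$behavior, "kaiser")
  B <- as.matrix(sim$cohort$behavior)
  dup <- B[c(1:10, 1:10), ]
  sc <- factor_scores(fm, dup)
  expect_equal(sc[1:10, ], sc[11:20, ])

  # identity-loading model: scores equal the standardized measures
  Z <- scale(B[, 1:3])
  toy <- structure(list(loadings = diag(3), score_weights = diag(3),
                        center = attr(Z, "scaled:center"),
                        scale = attr(Z, "scaled:scale"),
                        scores = matrix(0, 2, 3),
                        measures = colnames(B)[1:3], n_factors = 3),
                   class = "factor_model")
  expect_equal(unname(factor_scores(toy, B[, 1:3])), unname(Z[, 1:3]),
               ignore_attr = TRUE)

  expect_error(factor_scores(fm, B[, 1:5]), "do not match")
})

test_that("degenerate batteries are rejected", {
  B <- cbind(a = rep(1, 30), b = rnorm(30))
  expect_error(fit_pca_varimax(B), "constant measure")
  expect_error(fit_pca_varimax(matrix(rnorm(60), 20), n_factors = 5),
               "exceeds")
})

test_that("two-sided mapping is invariant to a factor's sign flip", {
  sim <- tiny_sim()
  co <- sim$cohort
  mask <- build_analysis_mask(co)
  X <- dtlvc_normalize(co, mask)
  y <- co$behavior$score
  a <- continuous_fwer_threshold(X, y, B = 200, seed = 5,
                                 alternative = "two.sided")
  b <- continuous_fwer_threshold(X, -y, B = 200, seed = 5,
                                 alternative = "two.sided")
  expect_identical(a$survivors, b$survivors)

  # nested-model statistics are sign-invariant too
  load <- sim$truth$region_loads[, "focal"]
  ca <- compare_models(y, co$sizes_cc, load)
  cb <- compare_models(-y, co$sizes_cc, load)
  expect_equal(ca$delta_r2, cb$delta_r2)
  expect_equal(ca$p_value, cb$p_value)
  expect_equal(abs(ca$partial_r), abs(cb$partial_r))
})
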