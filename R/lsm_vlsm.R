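# Column-standardize a matrix; zero-variance columns get scale NA and are
# reported via the "excluded" attribute (statistics there are undefined).
standardize_cols <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colSums(sweep(X, 2, mu)^2) / (nrow(X) - 1))
  bad <- as.integer(which(s == 0))
  s2 <- ifelse(s == 0, 1, s)
  Z <- sweep(sweep(X, 2, mu), 2, s2, "/")
  list(Z = Z, center = mu, scale = s2, excluded = bad)
}

t_from_r <- function(r, n, cap = 1e6) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pmin(pmax(t, -cap), cap)
}

#' Mass-univariate voxelwise lesion-symptom statistics
#'
#' For each in-mask voxel, the t-statistic of the slope from the simple
#' regression of the score on that voxel's (dTLVC-normalized) damage value
#' — equivalently the t-transform of the Pearson correlation. Scores are
#' coded higher = better, so damage that predicts lower scores yields a
#' negative statistic.
#'
#' @param X a [dtlvc_normalize()] result or plain n x p matrix.
#' @param y numeric score vector aligned with the rows of `X`.
#' @return Numeric vector of per-voxel t statistics (`NA` for zero-variance
#'   voxels, reported in attribute `"excluded"`); `|t|` is capped at `1e6`
#'   for numerically perfect associations.
#' @export
voxelwise_statistic <- function(X, y) {
  V <- lesion_values(X)
  stopifnot(nrow(V) == length(y))
  n <- nrow(V)
  st <- standardize_cols(V)
  yz <- (y - mean(y))
  ys <- sd(y)
  if (ys == 0) stop("score vector is constant")
  r <- as.numeric(crossprod(st$Z, yz)) / ((n - 1) * ys)
  t <- t_from_r(r, n)
  if (length(st$excluded) > 0) {
    warning(sprintf("%d zero-variance voxel(s) excluded", length(st$excluded)))
    t[st$excluded] <- NA_real_
  }
  structure(t, excluded = st$excluded)
}

# v-th most extreme statistic per permutation, in the testing direction.
order_stat_extreme <- function(M, v, alternative) {
  if (alternative == "two.sided") M <- -abs(M)
  apply(M, 2, function(x) sort(x, partial = v)[v])
}

# All permutations of 1..n as a list (n <= 8 guard lives in the caller).
enumerate_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0
  rec <- function(prefix, rest) {
    if (length(rest) == 0) { k <<- k + 1; out[[k]] <<- prefix; return() }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(n))
  out
}

#' Permutation-based continuous (generalized) FWER threshold
#'
#' Controls the probability of `v` or more false-positive voxels at level
#' `alpha`: for each permutation of the scores, all voxel statistics are
#' recomputed and the v-th most extreme value in the deficit direction is
#' recorded; the critical value is the nearest-rank alpha quantile of that
#' null distribution (`k = max(1, floor(alpha * (B + 1)))`-th smallest over
#' `B` Monte-carlo permutations, or `k = max(1, floor(alpha * n!))` under
#' exhaustive enumeration). With `v = 1` this is the classical single-step
#' max-statistic FWER correction. Because v was designed for full-brain
#' masks of roughly 150,000 voxels, `scale_v = TRUE` (default) rescales it
#' to the current mask: `v_eff = max(1, round(v * p / 150000))`.
#'
#' @param X a [dtlvc_normalize()] result or n x p matrix.
#' @param y score vector (higher = better; the test is one-sided toward
#'   damage -> lower scores unless `alternative = "two.sided"`).
#' @param B number of Monte-Carlo permutations (>= 100).
#' @param v order statistic of the generalized FWER (number of tolerated
#'   false-positive voxels), on the reference-mask scale.
#' @param alpha significance level.
#' @param seed integer seed for the permutation draws.
#' @param scale_v rescale `v` to the mask size (see above).
#' @param alternative `"less"` (deficit direction) or `"two.sided"`.
#' @param exact enumerate all `n!` permutations instead of sampling
#'   (requires `n <= 8`).
#' @return A `stat_map`: `statistic` (per in-mask voxel), `threshold`,
#'   `survivors` (positions within the mask), `survivor_voxels` (absolute
#'   voxel indices when `X` carries its mask), `null_dist`, and `params`.
#' @export
continuous_fwer_threshold <- function(X, y, B = 1000, v = 100, alpha = 0.05,
                                      seed = NULL, scale_v = TRUE,
                                      alternative = c("less", "two.sided"),
                                      exact = FALSE) {
  alternative <- match.arg(alternative)
  V <- lesion_values(X)
  mask <- lesion_mask_of(X)
  n <- nrow(V); p <- ncol(V)
  stopifnot(length(y) == n)
  if (!exact && B < 100) stop("B must be >= 100")
  v_eff <- if (scale_v) max(1L, as.integer(round(v * p / 150000))) else as.integer(v)
  if (v_eff > p) stop("v exceeds the number of in-mask voxels")

  if (sd(y) == 0) {
    # a constant score carries no lesion-symptom signal: empty result
    warning("score vector is constant; no voxel can be associated")
    return(structure(list(statistic = rep(NA_real_, p), threshold = -Inf,
                          survivors = integer(0),
                          survivor_voxels = integer(0),
                          null_dist = numeric(0), mask = mask,
                          params = list(B = B, v = v, v_eff = v_eff,
                                        alpha = alpha,
                                        alternative = alternative,
                                        exact = exact, seed = seed)),
                     class = "stat_map"))
  }

  st <- standardize_cols(V)
  keep <- setdiff(seq_len(p), st$excluded)
  if (length(st$excluded) > 0)
    warning(sprintf("%d zero-variance voxel(s) excluded", length(st$excluded)))
  Z <- st$Z[, keep, drop = FALSE]
  if (v_eff > ncol(Z)) stop("v exceeds the number of testable voxels")

  if (exact) {
    if (n > 8) stop("exact enumeration requires n <= 8")
    perms <- enumerate_perms(n)
    Y <- vapply(perms, function(pm) y[pm], numeric(n))
  } else {
    Y <- with_seed(seed, vapply(seq_len(B), function(b) y[sample.int(n)],
                                numeric(n)))
  }
  nb <- ncol(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ysd <- sqrt(colSums(Yc^2) / (n - 1))
  Yz <- sweep(Yc, 2, ifelse(ysd == 0, 1, ysd), "/")
  Rm <- crossprod(Z, Yz) / (n - 1)          # p_keep x nb correlations
  Tm <- t_from_r(Rm, n)
  null_v <- order_stat_extreme(Tm, v_eff, alternative)
  k <- if (exact) max(1L, as.integer(floor(alpha * nb)))
       else max(1L, as.integer(floor(alpha * (nb + 1))))
  threshold <- sort(null_v, partial = k)[k]

  t_obs <- rep(NA_real_, p)
  yz <- (y - mean(y)) / sd(y)
  t_obs[keep] <- t_from_r(as.numeric(crossprod(Z, yz)) / (n - 1), n)
  obs_cmp <- if (alternative == "two.sided") -abs(t_obs) else t_obs
  survivors <- which(!is.na(obs_cmp) & obs_cmp <= threshold)  # ties included

  structure(list(statistic = t_obs, threshold = threshold,
                 survivors = survivors,
                 survivor_voxels = if (!is.null(mask)) mask$voxels[survivors]
                                   else survivors,
                 null_dist = null_v, mask = mask,
                 params = list(B = nb, v = v, v_eff = v_eff, alpha = alpha,
                               alternative = alternative, exact = exact,
                               seed = seed)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d voxels, threshold %.3f (v_eff = %d, alpha = %.2f, B = %d), %d survivors\n",
              length(x$statistic), x$threshold, x$params$v_eff,
              x$params$alpha, x$params$B, length(x$survivors)))
  invisible(x)
}

#' Threshold a statistic map into a binary critical-region template
#'
#' @param statmap a [continuous_fwer_threshold()] result.
#' @return An `lsm_template`: surviving voxel indices (absolute if the stat
#'   map carries its analysis mask), `size`, and provenance. Empty
#'   templates are allowed.
#' @export
vlsm_template <- function(statmap) {
  stopifnot(inherits(statmap, "stat_map"))
  v <- statmap$survivor_voxels
  if (length(v) == 0) message("VLSM template is empty (no survivors)")
  structure(list(voxels = as.integer(v), size = length(v),
                 method = "vlsm", params = statmap$params),
            class = "lsm_template")
}

#' @export
print.lsm_template <- function(x, ...) {
  cat(sprintf("<lsm_template> %s, %d voxels\n", x$method, x$size))
  invisible(x)
}
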