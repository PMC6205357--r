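# 26-neighbour adjacency (as column positions) for the voxels of an
# analysis mask; used by the sparse fit's spatial smoothing prior.
mask_adjacency <- function(mask) {
  d <- mask$geometry$dims
  p <- length(mask$voxels)
  pos <- integer(prod(d))
  pos[mask$voxels] <- seq_len(p)
  co <- arrayInd(mask$voxels, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nb <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    sh <- sweep(co, 2, offs[i, ], "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    idx <- integer(p)
    idx[ok] <- pos[sh[ok, 1] + d[1] * (sh[ok, 2] - 1) +
                     d[1] * d[2] * (sh[ok, 3] - 1)]
    nb[[i]] <- idx             # 0 where neighbour outside mask
  }
  nb
}

# w -> (1 - lambda) w + lambda (neighbour mean of w) over the mask lattice.
smooth_weights <- function(w, adj, lambda) {
  if (lambda <= 0 || is.null(adj)) return(w)
  acc <- numeric(length(w)); cnt <- numeric(length(w))
  for (idx in adj) {
    has <- idx > 0
    acc[has] <- acc[has] + w[idx[has]]
    cnt[has] <- cnt[has] + 1
  }
  nbmean <- ifelse(cnt > 0, acc / pmax(cnt, 1), w)
  (1 - lambda) * w + lambda * nbmean
}

# Keep the k largest-magnitude entries of w, zero the rest, unit L2 norm.
truncate_normalize <- function(w, k) {
  p <- length(w)
  if (k < p) {
    drop <- order(abs(w), decreasing = TRUE)[(k + 1):p]
    w[drop] <- 0
  }
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("weight vector collapsed to zero")
  w / nw
}

#' Sparse multivariate lesion-symptom weight map (SCCAN-style)
#'
#' Estimates a sparse voxel-weight vector whose projection of the
#' (column-standardized) lesion matrix maximally correlates with the score.
#' The sparseness parameter `s` in (0, 1] sets the retained fraction of
#' mask voxels (`k = round(s * p)`); larger values are less sparse. The
#' estimate is a truncated-projection iteration: initialize `w` from the
#' voxel-score correlations, then alternately (i) keep the k largest
#' magnitudes, zero the rest and renormalize to unit L2 norm, and (ii)
#' recompute `w` from the correlation of each voxel with the score
#' component captured by the current projection, until the support is
#' stable (cap 100 iterations). With `s = 1` the constraint is inactive and
#' the closed-form `w` proportional to `X'y` is returned. Weights are
#' oriented so the projection correlates negatively with the score (damage
#' predicts deficit).
#'
#' An optional spatial smoothing prior (weight `smooth` on the 26-neighbour
#' mean, applied before each truncation when `X` carries its analysis mask)
#' regularizes the support toward spatially coherent clusters, in the
#' spirit of the smoothness penalties of sparse CCA implementations for
#' neuroimaging. It is off by default: it tightens support placement but
#' can trade away held-out prediction accuracy at small `s`.
#'
#' @param X a [dtlvc_normalize()] result or n x p matrix.
#' @param y score vector.
#' @param s sparseness in (0, 1].
#' @param max_iter support-stabilization cap.
#' @param smooth spatial smoothing weight in `[0, 1)`; 0 disables. Ignored
#'   (with no effect) when `X` is a bare matrix without mask geometry.
#' @return An `sccan_fit`: `weights` (length p, unit L2 norm), `support`
#'   (positions in mask), `support_voxels` (absolute indices if available),
#'   `s`, `k`, `iterations`, `converged`, plus the training
#'   standardization (`center`, `scale`) for out-of-sample projection.
#' @export
sccan_fit <- function(X, y, s, max_iter = 100, smooth = 0) {
  stopifnot(s > 0, s <= 1)
  V <- lesion_values(X)
  mask <- lesion_mask_of(X)
  n <- nrow(V); p <- ncol(V)
  stopifnot(length(y) == n)
  k <- as.integer(round(s * p))
  if (k < 1) stop("sparseness retains zero voxels")
  st <- standardize_cols(V)
  Z <- st$Z
  yc <- y - mean(y)
  if (sd(y) == 0) stop("score vector is constant")
  adj <- if (!is.null(mask) && smooth > 0 && k < p) mask_adjacency(mask) else NULL

  w <- as.numeric(crossprod(Z, yc)) / (n - 1)
  w[st$excluded] <- 0
  w <- smooth_weights(w, adj, smooth)
  w[st$excluded] <- 0
  w <- truncate_normalize(w, k)
  it <- 0L; converged <- TRUE
  if (k < p) {
    supp_old <- which(w != 0)
    converged <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      z <- as.numeric(Z %*% w)
      zz <- sum(z^2)
      if (zz == 0) break
      yhat <- z * (sum(yc * z) / zz)     # score component along the projection
      w_new <- as.numeric(crossprod(Z, yhat)) / (n - 1)
      w_new <- smooth_weights(w_new, adj, smooth)
      w_new[st$excluded] <- 0
      w_new <- truncate_normalize(w_new, k)
      supp_new <- which(w_new != 0)
      w <- w_new
      if (identical(supp_new, supp_old)) { converged <- TRUE; break }
      supp_old <- supp_new
    }
  }
  z <- as.numeric(Z %*% w)
  if (sd(z) > 0 && cor(z, y) > 0) w <- -w
  support <- which(w != 0)
  structure(list(weights = w, support = support,
                 support_voxels = if (!is.null(mask)) mask$voxels[support]
                                  else support,
                 s = s, k = k, iterations = it, converged = converged,
                 center = st$center, scale = st$scale, mask = mask),
            class = "sccan_fit")
}

#' @export
print.sccan_fit <- function(x, ...) {
  cat(sprintf("<sccan_fit> s = %.3f, support %d / %d voxels (%d iterations)\n",
              x$s, length(x$support), length(x$weights), x$iterations))
  invisible(x)
}

# Project held-out rows through a fit, on the training standardization.
sccan_project <- function(fit, Vnew) {
  Z <- sweep(sweep(Vnew, 2, fit$center), 2, fit$scale, "/")
  as.numeric(Z %*% fit$weights)
}

#' Cross-validated prediction accuracy of a sparse lesion-symptom fit
#'
#' Participants are split into `k` folds; per fold the weight map is fitted
#' on the training rows, held-out rows are projected through it, and the
#' projection is mapped to the score scale by the training-set linear
#' calibration (intercept + slope of the training scores on the training
#' projection). The CV correlation is the Pearson correlation between the
#' pooled held-out predictions and the observed scores.
#'
#' @param X a [dtlvc_normalize()] result or n x p matrix.
#' @param y score vector.
#' @param s sparseness in (0, 1].
#' @param k number of folds (default 4).
#' @param seed integer seed controlling the fold split.
#' @param smooth spatial smoothing weight passed to [sccan_fit()].
#' @return The pooled CV correlation, with the per-participant held-out
#'   predictions in attribute `"predictions"`.
#' @export
cv_correlation <- function(X, y, s, k = 4, seed = NULL, smooth = 0) {
  V <- lesion_values(X)
  mask <- lesion_mask_of(X)
  n <- nrow(V)
  stopifnot(k >= 2, k <= n)
  fold <- assign_folds(n, k, seed = seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    Xtr <- V[tr, , drop = FALSE]
    if (!is.null(mask))
      Xtr <- structure(list(values = Xtr, mask = mask), class = "dtlvc_matrix")
    fit <- sccan_fit(Xtr, y[tr], s, smooth = smooth)
    ztr <- sccan_project(fit, V[tr, , drop = FALSE])
    zte <- sccan_project(fit, V[te, , drop = FALSE])
    if (sd(ztr) == 0) { pred[te] <- mean(y[tr]); next }
    b <- coef(lm(y[tr] ~ ztr))
    pred[te] <- b[1] + b[2] * zte
  }
  if (sd(pred) == 0) stop("pooled held-out predictions have zero variance")
  structure(cor(pred, y), predictions = pred)
}

#' Optimize the sparseness parameter by cross-validation
#'
#' Evaluates the CV correlation over a sparseness grid (same fold split for
#' every grid value) and selects the smallest `s` whose CV correlation is
#' within `tolerance` of the maximum — a deliberate bias toward sparser
#' solutions. If the lesion-deficit association is focal, a small `s`
#' predicts as well as large ones and is selected; if the association is
#' diffuse (e.g. deficits driven by overall lesion size), only large `s`
#' reaches the best accuracy.
#'
#' @param X a [dtlvc_normalize()] result or n x p matrix.
#' @param y score vector.
#' @param grid sparseness values in (0, 1].
#' @param k inner folds (default 4).
#' @param tolerance allowed CV-correlation sacrifice for sparsity.
#' @param seed integer seed (fold split).
#' @param smooth spatial smoothing weight passed to [sccan_fit()].
#' @return A `sparseness_search`: `s_star`, `cv_correlation`, and the full
#'   `path` (data frame of `s`, `cv_r`, `k_voxels`).
#' @export
optimize_sparseness <- function(X, y, grid = c(0.005, 0.01, 0.02, 0.05, 0.1,
                                               0.2, 0.4, 0.6, 0.8, 1.0),
                                k = 4, tolerance = 0.02, seed = NULL,
                                smooth = 0) {
  stopifnot(length(grid) >= 1, all(grid > 0), all(grid <= 1))
  p <- ncol(lesion_values(X))
  grid <- sort(unique(grid))
  cv <- vapply(grid, function(s) {
    if (round(s * p) < 1) return(NA_real_)
    tryCatch(as.numeric(cv_correlation(X, y, s, k = k, seed = seed,
                                       smooth = smooth)),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(cv))) stop("CV correlation undefined for every grid value")
  best <- max(cv, na.rm = TRUE)
  ok <- which(!is.na(cv) & cv >= best - tolerance)
  s_star <- grid[min(ok)]
  structure(list(s_star = s_star, cv_correlation = cv[min(ok)],
                 path = data.frame(s = grid, cv_r = cv,
                                   k_voxels = round(grid * p))),
            class = "sparseness_search")
}

#' @export
print.sparseness_search <- function(x, ...) {
  cat(sprintf("<sparseness_search> s* = %.3f (CV r = %.3f)\n",
              x$s_star, x$cv_correlation))
  print(x$path, row.names = FALSE)
  invisible(x)
}

#' Binary template from a sparse weight map
#'
#' @param fit an [sccan_fit()] result.
#' @param min_weight retain only voxels with `|weight|` above this value
#'   (default 0: any nonzero weight).
#' @return An `lsm_template` (possibly empty).
#' @export
sccan_template <- function(fit, min_weight = 0) {
  stopifnot(inherits(fit, "sccan_fit"))
  sel <- which(abs(fit$weights) > min_weight)
  v <- if (!is.null(fit$mask)) fit$mask$voxels[sel] else sel
  if (length(v) == 0) message("SCCAN template is empty")
  structure(list(voxels = as.integer(v), size = length(v),
                 method = "sccan", params = list(s = fit$s, min_weight = min_weight)),
            class = "lsm_template")
}
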