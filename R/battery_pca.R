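#' PCA with varimax rotation of a behavioral battery
#'
#' Measures are z-scored, decomposed by principal components, components are
#' retained either by a fixed count or by the Kaiser rule (eigenvalue of the
#' correlation matrix > 1.0), and the retained loadings are varimax-rotated
#' with Kaiser row normalization. Per-participant factor scores use the
#' regression method. Loadings are correlations between measures and
#' components (eigenvector times sqrt eigenvalue) prior to rotation.
#'
#' @param battery participants x measures numeric table (no missing
#'   values).
#' @param n_factors integer count, or `"kaiser"` to retain eigenvalues
#'   > 1.0.
#' @return A `factor_model`: `loadings` (rotated), `rotation` (orthonormal),
#'   `eigenvalues` (all components), `variance_explained` (per retained
#'   factor, proportion of total variance), `scores`, `center`, `scale`,
#'   `score_weights`.
#' @export
fit_pca_varimax <- function(battery, n_factors = "kaiser") {
  B <- as.matrix(battery)
  if (anyNA(B)) stop("battery contains missing values")
  m <- ncol(B)
  sds <- apply(B, 2, sd)
  if (any(sds == 0)) stop(sprintf("constant measure column: %s",
                                  paste(colnames(B)[sds == 0], collapse = ", ")))
  Z <- scale(B)
  R <- crossprod(Z) / (nrow(Z) - 1)
  e <- eigen(R, symmetric = TRUE)
  eigenvalues <- e$values
  if (identical(n_factors, "kaiser")) {
    k <- sum(eigenvalues > 1.0)
    if (k == 0) stop("no component has eigenvalue > 1")
  } else {
    k <- as.integer(n_factors)
    if (k > m) stop("n_factors exceeds number of measures")
  }
  if (nrow(B) < k + 2) stop("need at least n_factors + 2 participants")
  A <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(k)]), k)
  rownames(A) <- colnames(Z)
  if (k > 1) {
    vr <- varimax(A, normalize = TRUE)
    L <- unclass(vr$loadings)
    Rot <- vr$rotmat
  } else {
    L <- A
    Rot <- matrix(1, 1, 1)
  }
  colnames(L) <- sprintf("F%d", seq_len(k))
  # regression-method score weights: R^{-1} L (applied to z-scored measures)
  W <- solve(R, L)
  scores <- Z %*% W
  scores <- sweep(scores, 2, colMeans(scores))
  structure(list(loadings = L, rotation = Rot, eigenvalues = eigenvalues,
                 variance_explained = colSums(L^2) / m,
                 scores = scores, score_weights = W,
                 center = attr(Z, "scaled:center"),
                 scale = attr(Z, "scaled:scale"),
                 measures = colnames(Z), n_factors = k),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d factors from %d measures; variance explained %s (total %.0f%%)\n",
              x$n_factors, length(x$measures),
              paste(sprintf("%.0f%%", 100 * x$variance_explained), collapse = "/"),
              100 * sum(x$variance_explained)))
  invisible(x)
}

#' Regression-method factor scores for (new) battery data
#'
#' @param model a [fit_pca_varimax()] result.
#' @param battery participants x measures table with the model's measure
#'   columns.
#' @return participants x factors score matrix (columns zero-mean for the
#'   fitting sample by construction of the model).
#' @export
factor_scores <- function(model, battery) {
  B <- as.matrix(battery)
  if (!is.null(colnames(B)) && !identical(colnames(B), model$measures)) {
    if (!all(model$measures %in% colnames(B)))
      stop("battery columns do not match the model's measures")
    B <- B[, model$measures, drop = FALSE]
  }
  if (ncol(B) != length(model$measures))
    stop("battery columns do not match the model's measures")
  Z <- scale(B, center = model$center, scale = model$scale)
  S <- Z %*% model$score_weights
  sweep(S, 2, colMeans(model$scores))
}

#' Tucker congruence between two loading matrices
#'
#' Per-column cosine similarity `sum(xy) / sqrt(sum(x^2) sum(y^2))` after
#' optimal sign/permutation alignment of the columns of `est` to `ref`
#' (alignment maximizes total absolute congruence; factors are sign- and
#' order-indeterminate).
#'
#' @param est,ref loading matrices with equal dimensions.
#' @param align if `TRUE` (default) search all column permutations and
#'   signs.
#' @return Numeric vector of per-factor congruences (in ref's column
#'   order), with the permutation used in attribute `"perm"`.
#' @export
tucker_congruence <- function(est, ref, align = TRUE) {
  est <- as.matrix(est); ref <- as.matrix(ref)
  stopifnot(identical(dim(est), dim(ref)))
  k <- ncol(ref)
  cong <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  C <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cong(est[, i], ref[, j])))
  if (!align) return(diag(C))
  perms <- permutations_of(k)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    v <- abs(C[cbind(p, seq_len(k))])
    if (sum(v) > best_val) { best_val <- sum(v); best <- p }
  }
  out <- abs(C[cbind(best, seq_len(k))])
  structure(out, perm = best)
}

# All permutations of 1..k (k small: factor counts).
permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- permutations_of(k - 1)
    for (r in rest) out[[length(out) + 1]] <- c(i, setdiff(seq_len(k), i)[r])
  }
  out
}
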