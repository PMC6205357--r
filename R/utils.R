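#' @useDynLib lesionmapr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm resid anova prcomp varimax sd rnorm rlnorm pf pt quantile coef var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation: one master integer seed fans out to
# independent streams (participants, folds, permutations). Kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.double(p)
    h <- (h * 69069 + v * 1234567 + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Dice overlap coefficient between two voxel sets
#'
#' `2|A n B| / (|A| + |B|)`; used to compare recovered lesion-symptom
#' templates with planted critical regions.
#'
#' @param a,b integer vectors of voxel linear indices (or objects with a
#'   `voxels` element, e.g. templates).
#' @return Dice coefficient in `[0, 1]`; `NA` if both sets are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- voxel_ids(a); b <- voxel_ids(b)
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Accept either a bare index vector or a list-like object carrying $voxels.
voxel_ids <- function(x) {
  if (is.list(x) && !is.null(x$voxels)) as.integer(x$voxels) else as.integer(x)
}
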