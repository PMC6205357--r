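#' Random balanced fold assignment
#'
#' @param n number of participants.
#' @param k number of folds (default 8; fold sizes differ by at most 1).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`, with attribute `"k"`.
#' @export
assign_folds <- function(n, k = 8, seed = NULL) {
  stopifnot(k >= 1, k <= n)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  structure(fold, k = k)
}

#' Template lesion load
#'
#' The proportion of an LSM-derived critical-region template that falls
#' within an individual's lesion: `|lesion n template| / |template|`. This
#' normalizes by template size, which varies across deficit scores and
#' folds.
#'
#' @param lesion a lesion mask (integer voxel indices, or an object with a
#'   `voxels` element).
#' @param template an `lsm_template` (or voxel index vector).
#' @return Load in `[0, 1]`. A size-0 template yields 0 with a warning.
#' @export
template_lesion_load <- function(lesion, template) {
  tv <- voxel_ids(template)
  if (length(tv) == 0) {
    warning("empty template: lesion load set to 0")
    return(0)
  }
  length(intersect(voxel_ids(lesion), tv)) / length(tv)
}

#' Cross-validated template lesion loads
#'
#' For each fold, lesion-symptom mapping is run on the training
#' participants only (analysis mask, dTLVC normalization and template all
#' rebuilt from the training set, unless `rebuild_mask = FALSE`), the
#' result is thresholded into a template, and the template lesion load is
#' computed for the held-out participants. No participant's load ever
#' derives from a template that saw their data.
#'
#' @param cohort a [lesion_cohort()].
#' @param scores named list (or n x d matrix/data frame) of deficit score
#'   vectors.
#' @param method `"vlsm"` or `"sccan"`.
#' @param folds an [assign_folds()] vector.
#' @param params method parameters: for vlsm `B`, `v`, `alpha`, `seed`; for
#'   sccan a named `s` vector (one per deficit, recycled if scalar; the
#'   full-sample optimal sparseness values are the intended input).
#' @param min_frequency analysis-mask threshold.
#' @param rebuild_mask rebuild the analysis mask per training fold
#'   (default) or reuse a fixed full-sample mask.
#' @return A `predictor_table`: `loads` (n x d matrix), `lesion_size_cc`,
#'   `template_sizes` (k x d), `templates` (per fold x deficit), `folds`.
#' @export
cross_validated_loads <- function(cohort, scores, method = c("vlsm", "sccan"),
                                  folds, params = list(),
                                  min_frequency = 0.10, rebuild_mask = TRUE) {
  method <- match.arg(method)
  S <- as.data.frame(scores)
  n <- length(cohort$masks)
  stopifnot(nrow(S) == n, length(folds) == n)
  k <- attr(folds, "k")
  if (is.null(k)) k <- max(folds)
  if (k < 2) stop("need at least 2 folds")
  loads <- matrix(NA_real_, n, ncol(S), dimnames = list(cohort$ids, names(S)))
  tsize <- matrix(NA_integer_, k, ncol(S), dimnames = list(NULL, names(S)))
  templates <- vector("list", k)
  full_mask <- if (!rebuild_mask) build_analysis_mask(cohort, min_frequency) else NULL
  seed <- if (is.null(params$seed)) 0L else params$seed

  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    train <- cohort[tr]
    mask <- if (rebuild_mask) build_analysis_mask(train, min_frequency) else full_mask
    Xtr <- dtlvc_normalize(train, mask)
    templates[[f]] <- vector("list", ncol(S))
    names(templates[[f]]) <- names(S)
    for (d in seq_len(ncol(S))) {
      y <- S[tr, d]
      tmpl <- if (method == "vlsm") {
        sm <- continuous_fwer_threshold(
          Xtr, y,
          B = if (is.null(params$B)) 1000 else params$B,
          v = if (is.null(params$v)) 100 else params$v,
          alpha = if (is.null(params$alpha)) 0.05 else params$alpha,
          seed = derive_seed(seed, "fwer", f, d))
        vlsm_template(sm)
      } else {
        s <- params$s
        if (is.null(s)) stop("sccan loads need a sparseness value per deficit")
        s <- rep(s, length.out = ncol(S))
        if (!is.null(names(params$s)) && all(names(S) %in% names(params$s)))
          s <- params$s[names(S)]
        suppressMessages(sccan_template(sccan_fit(Xtr, y, s[[d]])))
      }
      templates[[f]][[d]] <- tmpl
      tsize[f, d] <- tmpl$size
      for (i in te)
        loads[i, d] <- suppressWarnings(
          template_lesion_load(cohort$masks[[i]], tmpl))
    }
  }
  structure(list(loads = loads, lesion_size_cc = cohort$sizes_cc,
                 template_sizes = tsize, templates = templates,
                 folds = folds, method = method),
            class = "predictor_table")
}

#' Nested-regression comparison of lesion size and template lesion load
#'
#' Fits three ordinary least squares models of the deficit score —
#' size-only, load-only, and size + load (predictors z-scored) — and tests
#' whether lesion location adds predictive value beyond lesion size: the
#' nested F test of (size + load) vs (size) with 1 and n - 3 df, plus the
#' partial correlation of load and score controlling for size
#' (residual-residual correlation).
#'
#' @param score deficit score vector.
#' @param size_cc lesion sizes in cc.
#' @param load template lesion loads in `[0, 1]`.
#' @return A `model_comparison`: `r2_size`, `r2_load`, `r2_both`,
#'   `delta_r2`, `f_stat`, `p_value`, `partial_r`, `partial_p`, `n`,
#'   `degenerate`.
#' @export
compare_models <- function(score, size_cc, load) {
  n <- length(score)
  stopifnot(length(size_cc) == n, length(load) == n, n >= 4)
  degenerate <- character(0)
  zsize <- zscore(size_cc); zload <- zscore(load)
  if (sd(size_cc) == 0) degenerate <- c(degenerate, "size")
  if (sd(load) == 0) degenerate <- c(degenerate, "load")
  r2 <- function(m) summary(m)$r.squared
  m_size <- lm(score ~ zsize)
  m_load <- lm(score ~ zload)
  m_both <- lm(score ~ zsize + zload)
  r2_size <- if ("size" %in% degenerate) 0 else r2(m_size)
  r2_load <- if ("load" %in% degenerate) 0 else r2(m_load)
  r2_both <- r2(m_both)
  if (length(degenerate) > 0) warning(sprintf(
    "degenerate (constant) predictor: %s", paste(degenerate, collapse = ", ")))
  if ("load" %in% degenerate || abs(cor(zsize, zload)) > 1 - 1e-12) {
    delta_r2 <- 0; f_stat <- 0; p_value <- 1; partial_r <- 0; partial_p <- 1
  } else {
    a <- anova(m_size, m_both)
    delta_r2 <- r2_both - r2_size
    f_stat <- a$F[2]; p_value <- a$`Pr(>F)`[2]
    rs <- resid(lm(score ~ zsize)); rl <- resid(lm(zload ~ zsize))
    partial_r <- cor(rs, rl)
    tt <- partial_r * sqrt((n - 3) / max(1 - partial_r^2, .Machine$double.eps))
    partial_p <- 2 * pt(-abs(tt), df = n - 3)
  }
  structure(list(r2_size = r2_size, r2_load = r2_load, r2_both = r2_both,
                 delta_r2 = delta_r2, f_stat = f_stat, p_value = p_value,
                 partial_r = partial_r, partial_p = partial_p, n = n,
                 degenerate = degenerate),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(paste0("<model_comparison> R2 size %.3f | load %.3f | both %.3f;",
                     " dR2 %.3f (F = %.2f, p = %.3g); partial r %.3f\n"),
              x$r2_size, x$r2_load, x$r2_both, x$delta_r2, x$f_stat,
              x$p_value, x$partial_r))
  invisible(x)
}

#' Residualize deficit scores on lesion size (behavior-side control)
#'
#' Returns the residuals of the score regressed on lesion size (intercept
#' included): a conservative control that attributes as much deficit
#' variance as possible to lesion size before mapping.
#'
#' @param score deficit score vector.
#' @param size_cc lesion sizes in cc.
#' @return Residual score vector (mean 0, uncorrelated with size).
#' @export
behavior_residual_control <- function(score, size_cc) {
  as.numeric(resid(lm(score ~ size_cc)))
}

#' End-to-end cross-validated lesion-load prediction study
#'
#' The full pipeline for one or more deficit scores: participants are
#' partitioned into `k` folds (default 8); per fold, lesion-symptom mapping
#' (VLSM with continuous FWER and/or SCCAN at fixed sparseness) is run on
#' the training set and thresholded into a template; template lesion load
#' is computed for held-out participants; and per deficit the nested
#' regression of [compare_models()] quantifies whether lesion location
#' (load) predicts the deficit beyond lesion size. For SCCAN, if no
#' sparseness values are supplied they are first optimized on the full
#' sample.
#'
#' @param cohort a [lesion_cohort()].
#' @param deficits named list / data frame of score vectors (defaults to
#'   all columns of `cohort$behavior`).
#' @param methods subset of `c("vlsm", "sccan")`.
#' @param config list of parameters: `k` (folds, 8), `B` (permutations,
#'   1000), `v` (100), `alpha` (0.05), `sccan_s` (named sparseness vector,
#'   or `NULL` to optimize), `grid`, `tolerance` (0.02), `k_inner` (4),
#'   `min_frequency` (0.1), `rebuild_mask` (TRUE), `seed`.
#' @return A `study2_result`: `comparisons` (long data frame over method x
#'   deficit), `predictors` (per-method [cross_validated_loads()] output),
#'   `sccan_s`, `folds`, `config`.
#' @export
run_study2 <- function(cohort, deficits = NULL,
                       methods = c("vlsm", "sccan"), config = list()) {
  defaults <- list(k = 8, B = 1000, v = 100, alpha = 0.05, sccan_s = NULL,
                   grid = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                   tolerance = 0.02, k_inner = 4, min_frequency = 0.10,
                   rebuild_mask = TRUE, seed = 1)
  config <- utils::modifyList(defaults, config)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(deficits)) deficits <- cohort$behavior
  S <- as.data.frame(deficits)
  n <- length(cohort$masks)
  folds <- assign_folds(n, config$k, seed = derive_seed(config$seed, "folds"))

  sccan_s <- config$sccan_s
  if ("sccan" %in% methods && is.null(sccan_s)) {
    # full-sample optimal sparseness, reused across folds for consistency
    mask <- build_analysis_mask(cohort, config$min_frequency)
    Xfull <- dtlvc_normalize(cohort, mask)
    sccan_s <- vapply(names(S), function(d)
      optimize_sparseness(Xfull, S[[d]], grid = config$grid,
                          k = config$k_inner, tolerance = config$tolerance,
                          seed = derive_seed(config$seed, "sgrid", d))$s_star,
      numeric(1))
  }

  predictors <- list(); rows <- list()
  for (m in methods) {
    params <- if (m == "vlsm")
      list(B = config$B, v = config$v, alpha = config$alpha,
           seed = derive_seed(config$seed, "vlsm"))
    else list(s = sccan_s)
    pt <- cross_validated_loads(cohort, S, method = m, folds = folds,
                                params = params,
                                min_frequency = config$min_frequency,
                                rebuild_mask = config$rebuild_mask)
    predictors[[m]] <- pt
    for (d in names(S)) {
      cmp <- suppressWarnings(
        compare_models(S[[d]], cohort$sizes_cc, pt$loads[, d]))
      rows[[paste(m, d)]] <- data.frame(
        method = m, deficit = d, r2_size = cmp$r2_size, r2_load = cmp$r2_load,
        r2_both = cmp$r2_both, delta_r2 = cmp$delta_r2, f_stat = cmp$f_stat,
        p_value = cmp$p_value, partial_r = cmp$partial_r,
        significant = cmp$p_value < config$alpha,
        mean_template_voxels = mean(pt$template_sizes[, d]))
    }
  }
  structure(list(comparisons = do.call(rbind, c(rows, make.row.names = FALSE)),
                 predictors = predictors, sccan_s = sccan_s, folds = folds,
                 config = config),
            class = "study2_result")
}

#' @export
print.study2_result <- function(x, ...) {
  cat(sprintf("<study2_result> %d folds, seed %d\n", x$config$k, x$config$seed))
  print(x$comparisons, row.names = FALSE, digits = 3)
  invisible(x)
}
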