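#' Build a vascular-territory probability field
#'
#' An anisotropic Gaussian field truncated at a Mahalanobis radius, standing
#' in for the left middle-cerebral-artery territory in which most
#' aphasia-causing stroke lesions concentrate. Lesion seeds and growth are
#' sampled proportionally to this field, so simulated cohorts show the
#' characteristic centre-heavy lesion-overlap pattern.
#'
#' @param geometry a [volume_geometry()].
#' @param center territory centre in voxel coordinates (default: mid-grid in
#'   y/z, one third along x, i.e. one hemisphere).
#' @param scale per-axis Gaussian scale in voxels.
#' @param cutoff Mahalanobis radius beyond which probability is exactly 0
#'   (defines a single connected, ellipsoidal support).
#' @return A `territory`: probability array (`prob`), `support` voxel
#'   indices, `center`, `geometry`.
#' @export
make_territory <- function(geometry, center = NULL, scale = NULL, cutoff = 2) {
  stopifnot(inherits(geometry, "volume_geometry"), cutoff > 0)
  d <- geometry$dims
  if (is.null(center)) center <- c(round(d[1] * 0.35), round(d[2] / 2), round(d[3] / 2))
  if (is.null(scale)) scale <- pmax(d / 5, 1)
  stopifnot(length(center) == 3, length(scale) == 3)
  if (any(scale <= 0)) stop("territory has empty support (non-positive scale)")
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  m2 <- ((g$x - center[1]) / scale[1])^2 + ((g$y - center[2]) / scale[2])^2 +
    ((g$z - center[3]) / scale[3])^2
  prob <- ifelse(m2 <= cutoff^2, exp(-0.5 * m2), 0)
  support <- which(prob > 0)
  if (length(support) == 0) stop("territory has empty support")
  structure(list(geometry = geometry, prob = array(prob, dim = d),
                 support = as.integer(support), center = center),
            class = "territory")
}

#' Plant a compact critical region inside a territory
#'
#' Selects the `size` support voxels closest to a centre point: a quasi-
#' spherical, connected region placed where lesions are frequent, used as
#' the ground-truth substrate of a focal deficit or latent factor.
#'
#' @param territory a [make_territory()] result.
#' @param size region size in voxels.
#' @param offset voxel offset of the region centre from the territory
#'   centre.
#' @return Sorted integer voxel indices of the region.
#' @export
plant_critical_region <- function(territory, size, offset = c(0, 0, 0)) {
  stopifnot(inherits(territory, "territory"), size >= 1)
  d <- territory$geometry$dims
  ctr <- territory$center + offset
  sup <- territory$support
  co <- arrayInd(sup, d)
  dist2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
  if (size > length(sup)) stop("region size exceeds territory support")
  sort(sup[order(dist2)][seq_len(size)])
}

#' Grow one synthetic lesion by stochastic region growing
#'
#' Starting from a seed voxel sampled proportionally to the territory
#' probability, voxels are added one at a time by sampling the 26-connected
#' frontier proportionally to territory probability, until exactly
#' `target_size` voxels are lesioned. Larger lesions therefore engulf more
#' of any critical region — reproducing the size-location coupling that
#' confounds lesion-symptom inference.
#'
#' @param territory a [make_territory()] result.
#' @param target_size lesion size in voxels (must not exceed the support).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param compactness surface-tension exponent: frontier voxels are sampled
#'   with weight `territory probability x (lesioned-neighbour count)^
#'   compactness`, so concavities fill first and lesions are spatially
#'   coherent like vascular infarcts; 0 gives rough Eden-style growth.
#' @return Sorted integer voxel indices of the lesion (length
#'   `target_size`).
#' @export
simulate_lesion <- function(territory, target_size, seed = NULL,
                            compactness = 2) {
  stopifnot(inherits(territory, "territory"), target_size >= 1,
            compactness >= 0)
  if (target_size > length(territory$support))
    stop("territory support exhausted before target size")
  with_seed(seed, {
    s <- territory$support[sample.int(length(territory$support), 1,
                                      prob = territory$prob[territory$support])]
    v <- grow_lesion_cpp(as.numeric(territory$prob), territory$geometry$dims,
                         s, as.integer(target_size), compactness)
    if (length(v) < target_size)
      stop("territory support exhausted before target size")
    sort(as.integer(v))
  })
}

# Truncated lognormal lesion sizes in cc (rejection sampling).
sample_sizes_cc <- function(n, meanlog, sdlog, min_cc, max_cc) {
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    x <- rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x >= min_cc & x <= max_cc])
    tries <- tries + 1
    if (tries > 200) stop("size bounds reject nearly all draws; check config")
  }
  out[seq_len(n)]
}

# Fraction of each region's voxels damaged, per participant.
compute_region_loads <- function(masks, regions, n_vox) {
  hit <- logical(n_vox)
  out <- matrix(0, length(masks), length(regions),
                dimnames = list(NULL, names(regions)))
  for (i in seq_along(masks)) {
    hit[masks[[i]]] <- TRUE
    for (j in seq_along(regions))
      out[i, j] <- mean(hit[regions[[j]]])
    hit[masks[[i]]] <- FALSE
  }
  out
}

#' Default battery loading matrix
#'
#' Simple-structure loadings for a measures x factors planted factor model:
#' each measure loads 0.8 on its primary factor and 0.1 elsewhere. With the
#' default 17 measures and 3 factors, blocks of 6/6/5 measures per factor.
#'
#' @param n_measures,n_factors battery dimensions.
#' @param primary,cross primary and cross loading values.
#' @return `n_measures` x `n_factors` matrix.
#' @export
default_loadings <- function(n_measures = 17, n_factors = 3,
                             primary = 0.8, cross = 0.1) {
  sizes <- rep(n_measures %/% n_factors, n_factors)
  rem <- n_measures %% n_factors
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  fac <- rep(seq_len(n_factors), times = sizes)
  L <- matrix(cross, n_measures, n_factors)
  L[cbind(seq_len(n_measures), fac)] <- primary
  rownames(L) <- sprintf("m%02d", seq_len(n_measures))
  colnames(L) <- sprintf("F%d", seq_len(n_factors))
  L
}

#' Scenario configuration for synthetic cohorts
#'
#' Bundles every generator parameter: geometry, territory field, lesion-size
#' distribution, deficit models and battery structure. The default lesion
#' sizes follow a lognormal calibrated to a chronic left-hemisphere stroke
#' cohort (mean 100.97 cc, SD 82.76 cc, range 5.38-376.12 cc; lognormal
#' meanlog 4.3578, sdlog 0.7170) with volumes scaled by `size_scale`
#' (default 1/32) so lesion extent relative to the territory preserves the
#' focal-vs-diffuse distinction on the desk-scale default grid (32^3
#' voxels at 2 mm).
#'
#' @param n number of participants.
#' @param dims,voxel_size grid geometry.
#' @param territory list with `center`, `scale`, `cutoff` (NULL entries =
#'   [make_territory()] defaults).
#' @param size_cc list with `meanlog`, `sdlog`, `min`, `max` in cc.
#' @param size_scale multiplicative volume scale applied to `size_cc`
#'   defaults (ignored if `size_cc` given).
#' @param regions named list of critical-region specs, each
#'   `list(size = voxels, offset = c(dx, dy, dz))`.
#' @param deficits named list of deficit models, each
#'   `list(w_size, w_focal, noise_sd, region = <region name or NULL>)`.
#' @param battery `NULL`, or a list with `loadings` (measures x factors),
#'   `uniqueness_sd`, `factor_regions` (character, one region name per
#'   factor), `orthogonalize` (default `TRUE`).
#' @param compactness lesion-growth surface tension (see
#'   [simulate_lesion()]).
#' @param seed master integer seed; every stream derives from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n = 128, dims = c(32, 32, 32), voxel_size = c(2, 2, 2),
                            territory = list(center = NULL, scale = NULL, cutoff = 2),
                            size_cc = NULL, size_scale = 1 / 32,
                            regions = list(focal = list(size = 25, offset = c(0, 0, 0))),
                            deficits = list(score = list(w_size = 0, w_focal = 1,
                                                         noise_sd = 1, region = "focal")),
                            battery = NULL, compactness = 2, seed = 1) {
  if (is.null(size_cc))
    size_cc <- list(meanlog = 4.3578 + log(size_scale), sdlog = 0.7170,
                    min = 5.38 * size_scale, max = 376.12 * size_scale)
  for (d in deficits) {
    stopifnot(d$w_size >= 0, d$w_focal >= 0, d$noise_sd >= 0)
    if (d$w_focal > 0 && (is.null(d$region) || !d$region %in% names(regions)))
      stop("focal deficit model needs a named planted region")
  }
  structure(list(n = as.integer(n),
                 geometry = volume_geometry(dims, voxel_size),
                 territory = territory, size_cc = size_cc, regions = regions,
                 deficits = deficits, battery = battery,
                 compactness = compactness, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Preset scenarios
#'
#' `scenario_focal()`: deficit driven purely by damage to a compact planted
#' region (~1% of the analysis mask) plus noise (generative R^2 = w^2 /
#' (w^2 + sigma^2) = 0.5 at the defaults). `scenario_size_driven()`: deficit
#' driven purely by overall lesion size. `scenario_null()`: pure noise.
#' `scenario_battery()`: adds a 17-measure battery with 3 planted orthogonal
#' factors tied to three disjoint critical regions.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param noise_sd deficit noise standard deviation (score units).
#' @name scenarios
#' @export
scenario_focal <- function(n = 128, seed = 1, noise_sd = 1) {
  scenario_config(n = n, seed = seed,
                  regions = list(focal = list(size = 25, offset = c(0, 0, 0))),
                  deficits = list(score = list(w_size = 0, w_focal = 1,
                                               noise_sd = noise_sd, region = "focal")))
}

#' @rdname scenarios
#' @export
scenario_size_driven <- function(n = 128, seed = 1, noise_sd = 1) {
  scenario_config(n = n, seed = seed,
                  deficits = list(score = list(w_size = 1, w_focal = 0,
                                               noise_sd = noise_sd)))
}

#' @rdname scenarios
#' @export
scenario_null <- function(n = 128, seed = 1) {
  scenario_config(n = n, seed = seed,
                  deficits = list(score = list(w_size = 0, w_focal = 0,
                                               noise_sd = 1)))
}

#' @rdname scenarios
#' @export
scenario_battery <- function(n = 128, seed = 1) {
  scenario_config(
    n = n, seed = seed,
    regions = list(r1 = list(size = 40, offset = c(0, -5, 0)),
                   r2 = list(size = 40, offset = c(0, 5, 0)),
                   r3 = list(size = 40, offset = c(0, 0, 5))),
    deficits = list(),
    battery = list(loadings = default_loadings(17, 3),
                   uniqueness_sd = 0.53,
                   factor_regions = c("r1", "r2", "r3"),
                   orthogonalize = TRUE))
}

#' Generate deficit scores from lesion size and focal damage
#'
#' `score_i = c - w_size * z(size_i) - w_focal * z(load_i) + eps_i`, with
#' `eps ~ N(0, noise_sd)`, `load_i` the damaged fraction of the critical
#' region and `z` the cohort z-score. Higher scores mean better performance
#' (accuracy-style coding), so damage lowers scores.
#'
#' @param cohort a [lesion_cohort()].
#' @param deficit_model list with `w_size`, `w_focal`, `noise_sd`, optional
#'   `intercept` (default 0) and `critical_region` (voxel indices; required
#'   if `w_focal > 0`).
#' @param seed optional integer seed.
#' @return Numeric score vector, with the noiseless component in attribute
#'   `"signal"`.
#' @export
generate_deficits <- function(cohort, deficit_model, seed = NULL) {
  n <- length(cohort$masks)
  zsize <- zscore(cohort$sizes_cc)
  zload <- 0
  if (deficit_model$w_focal > 0) {
    region <- deficit_model$critical_region
    stopifnot(!is.null(region))
    load <- compute_region_loads(cohort$masks, list(r = region),
                                 n_voxels(cohort$geometry))[, 1]
    zload <- zscore(load)
  }
  c0 <- if (is.null(deficit_model$intercept)) 0 else deficit_model$intercept
  signal <- c0 - deficit_model$w_size * zsize - deficit_model$w_focal * zload
  eps <- with_seed(seed, rnorm(n, 0, deficit_model$noise_sd))
  structure(signal + eps, signal = signal)
}

zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a multi-measure battery with planted factor structure
#'
#' Latent factors are built from the damaged fractions of per-factor
#' critical regions (z-scored; by default ZCA-orthogonalized so the planted
#' factors are exactly uncorrelated in-sample, matching the orthogonal
#' generative model `measures = F Lambda' + E`). Measure j then equals the
#' loading-weighted sum of latents plus independent Gaussian uniqueness
#' noise.
#'
#' @param region_loads participants x factor-regions matrix of damaged
#'   fractions (one column per factor).
#' @param battery_spec list with `loadings` (measures x factors),
#'   `uniqueness_sd` (scalar or per-measure), `orthogonalize` (default
#'   `TRUE`).
#' @param seed optional integer seed.
#' @return List with `measures` (n x m matrix, columns `m01`...) and
#'   `latents` (n x factors).
#' @export
generate_battery <- function(region_loads, battery_spec, seed = NULL) {
  L <- as.matrix(battery_spec$loadings)
  f <- ncol(L)
  stopifnot(ncol(region_loads) == f)
  Z <- apply(region_loads, 2, zscore)
  orth <- if (is.null(battery_spec$orthogonalize)) TRUE else battery_spec$orthogonalize
  if (orth && nrow(Z) > f) {
    C <- crossprod(scale(Z, scale = FALSE)) / (nrow(Z) - 1)
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) < 1e-10) stop("factor-region loads are collinear")
    W <- e$vectors %*% diag(1 / sqrt(e$values), f) %*% t(e$vectors)
    Z <- Z %*% W   # ZCA: unit covariance, maximally close to the raw loads
  }
  psd <- rep(battery_spec$uniqueness_sd, length.out = nrow(L))
  E <- with_seed(seed, matrix(rnorm(nrow(Z) * nrow(L)), nrow(Z)) %*% diag(psd))
  M <- Z %*% t(L) + E
  colnames(M) <- if (!is.null(rownames(L))) rownames(L) else
    sprintf("m%02d", seq_len(nrow(L)))
  list(measures = M, latents = Z)
}

#' Simulate a full lesion cohort with ground truth
#'
#' Draws lesion sizes from the configured truncated lognormal, grows each
#' lesion by stochastic region growing in the territory, computes planted
#' critical-region damage, and fills the behavior table with deficit scores
#' and (optionally) a planted-factor battery. Everything is reproducible
#' from `config$seed`.
#'
#' @param config a [scenario_config()].
#' @return List with `cohort` (a [lesion_cohort()]) and `truth` (regions,
#'   region loads, latent factors, generative weights, sizes, territory).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n < 1) stop("n must be >= 1")
  g <- config$geometry
  terr <- make_territory(g, center = config$territory$center,
                         scale = config$territory$scale,
                         cutoff = config$territory$cutoff)
  vv <- voxel_volume_cc(g)
  max_vox <- ceiling(config$size_cc$max / vv)
  if (max_vox > length(terr$support))
    stop(sprintf("size bound (%d voxels) exceeds territory support (%d voxels)",
                 max_vox, length(terr$support)))
  sizes_cc <- with_seed(derive_seed(config$seed, "sizes"),
                        sample_sizes_cc(config$n, config$size_cc$meanlog,
                                        config$size_cc$sdlog,
                                        config$size_cc$min, config$size_cc$max))
  sizes_vox <- pmax(1L, as.integer(round(sizes_cc / vv)))
  masks <- lapply(seq_len(config$n), function(i)
    simulate_lesion(terr, sizes_vox[i], seed = derive_seed(config$seed, "lesion", i),
                    compactness = config$compactness))
  regions <- lapply(config$regions, function(r)
    plant_critical_region(terr, r$size, r$offset))
  loads <- if (length(regions) > 0)
    compute_region_loads(masks, regions, n_voxels(g)) else NULL

  cohort <- lesion_cohort(g, masks)
  behavior <- data.frame(row.names = cohort$ids)
  for (nm in names(config$deficits)) {
    dm <- config$deficits[[nm]]
    if (dm$w_focal > 0) dm$critical_region <- regions[[dm$region]]
    behavior[[nm]] <- as.numeric(generate_deficits(
      cohort, dm, seed = derive_seed(config$seed, "deficit", nm)))
  }
  latents <- NULL
  if (!is.null(config$battery)) {
    fr <- config$battery$factor_regions
    bat <- generate_battery(loads[, fr, drop = FALSE], config$battery,
                            seed = derive_seed(config$seed, "battery"))
    behavior <- cbind(behavior, as.data.frame(bat$measures))
    latents <- bat$latents
  }
  cohort$behavior <- behavior
  truth <- list(regions = regions, region_loads = loads,
                latent_factors = latents, deficit_models = config$deficits,
                battery = config$battery, sizes_vox = sizes_vox,
                territory = terr, seed = config$seed)
  list(cohort = cohort, truth = truth)
}
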