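#' Volume geometry of a common analysis space
#'
#' All lesion masks in a cohort must share one geometry bit-for-bit: grid
#' dimensions, voxel size in mm, and the voxel-to-world affine. Synthetic
#' cohorts default to a desk-scale grid; real data carry the geometry of
#' their NIfTI headers.
#'
#' @param dims integer triple, voxels per axis (all >= 1).
#' @param voxel_size numeric triple, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default is a scaled identity
#'   placing the first voxel at the origin.
#' @return A `volume_geometry` object.
#' @export
volume_geometry <- function(dims, voxel_size = c(2, 2, 2), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1),
            length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %s voxels @ %s mm (%.3f cc/voxel)\n",
              paste(x$dims, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              voxel_volume_cc(x)))
  invisible(x)
}

# voxel volume in cc (1 cc = 1000 mm^3)
voxel_volume_cc <- function(geometry) prod(geometry$voxel_size) / 1000

n_voxels <- function(geometry) prod(geometry$dims)

same_geometry <- function(a, b, tol = 1e-4) {
  identical(a$dims, b$dims) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$affine - b$affine) < tol)
}

geometry_from_nifti <- function(img) {
  dims <- dim(img)
  stopifnot(length(dims) == 3)
  volume_geometry(dims, voxel_size = RNifti::pixdim(img)[1:3],
                  affine = structure(RNifti::xform(img), code = NULL))
}

#' Construct a lesion cohort from in-memory masks
#'
#' The common container for all downstream analyses: an ordered set of
#' binary lesion masks in one geometry, per-participant lesion sizes in cc,
#' and a participants x measures behavioral table. Masks are stored as
#' sorted 1-based linear voxel indices.
#'
#' @param geometry a [volume_geometry()].
#' @param masks list of binary 3D arrays, or of integer index vectors.
#' @param ids character participant identifiers (defaults to `sub001`...).
#' @param behavior data frame with one row per participant (first column is
#'   taken as the participant id if named `participant_id`).
#' @return A `lesion_cohort` with elements `geometry`, `ids`, `masks`
#'   (index vectors), `sizes_cc`, `behavior`.
#' @export
lesion_cohort <- function(geometry, masks, ids = NULL, behavior = NULL) {
  stopifnot(inherits(geometry, "volume_geometry"), length(masks) >= 1)
  n <- length(masks)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(n))
  stopifnot(length(ids) == n)
  idx <- lapply(seq_len(n), function(i) {
    m <- masks[[i]]
    if (is.array(m)) {
      if (!identical(dim(m), as.integer(geometry$dims)))
        stop(sprintf("mask %s: geometry mismatch (dims %s, expected %s)",
                     ids[i], paste(dim(m), collapse = "x"),
                     paste(geometry$dims, collapse = "x")))
      v <- as.numeric(m)
      if (any(v != 0 & v != 1))
        stop(sprintf("mask %s: non-binary values found", ids[i]))
      m <- which(v == 1)
    }
    m <- sort(unique(as.integer(m)))
    if (length(m) == 0) stop(sprintf("mask %s has no lesioned voxels", ids[i]))
    if (m[1] < 1 || m[length(m)] > n_voxels(geometry))
      stop(sprintf("mask %s: voxel index out of range", ids[i]))
    m
  })
  sizes_cc <- vapply(idx, length, 1L) * voxel_volume_cc(geometry)
  if (!is.null(behavior)) {
    behavior <- as.data.frame(behavior)
    if (nrow(behavior) != n)
      stop(sprintf("behavior table has %d rows for %d masks", nrow(behavior), n))
  }
  structure(list(geometry = geometry, ids = as.character(ids), masks = idx,
                 sizes_cc = sizes_cc, behavior = behavior),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("<lesion_cohort> n = %d, lesion size %.2f-%.2f cc (mean %.2f)\n",
              length(x$masks), min(x$sizes_cc), max(x$sizes_cc),
              mean(x$sizes_cc)))
  print(x$geometry)
  if (!is.null(x$behavior))
    cat(sprintf("  behavior: %d measures\n", ncol(x$behavior)))
  invisible(x)
}

#' Load a lesion cohort from NIfTI masks and a behavior table
#'
#' Reads per-participant binary lesion masks (all in one common space) and a
#' CSV behavior table with a header row whose first column is
#' `participant_id`. Masks must be strictly binary; any other value is an
#' error (no silent thresholding). Lesion sizes are computed as
#' nonzero-voxel count x voxel volume / 1000 (cc).
#'
#' @param mask_paths character vector of `.nii`/`.nii.gz` paths, one per
#'   participant, in cohort order.
#' @param behavior_path path to the behavior CSV (one row per mask, same
#'   order), or `NULL`.
#' @return A [lesion_cohort()].
#' @export
load_cohort <- function(mask_paths, behavior_path = NULL) {
  stopifnot(length(mask_paths) >= 1)
  ref <- NULL
  masks <- vector("list", length(mask_paths))
  ids <- sub("\\.nii(\\.gz)?$", "", basename(mask_paths))
  for (i in seq_along(mask_paths)) {
    img <- RNifti::readNifti(mask_paths[i])
    g <- geometry_from_nifti(img)
    if (is.null(ref)) ref <- g
    else if (!same_geometry(ref, g))
      stop(sprintf("geometry mismatch in %s", mask_paths[i]))
    v <- as.numeric(img)
    if (any(abs(v) > 1e-8 & abs(v - 1) > 1e-8))
      stop(sprintf("mask %s: non-binary values found", mask_paths[i]))
    w <- which(v > 0.5)
    if (length(w) == 0) stop(sprintf("mask %s has no lesioned voxels", mask_paths[i]))
    masks[[i]] <- w
  }
  behavior <- NULL
  if (!is.null(behavior_path)) {
    behavior <- read.csv(behavior_path, check.names = FALSE)
    if (nrow(behavior) != length(mask_paths))
      stop(sprintf("behavior table has %d rows for %d masks",
                   nrow(behavior), length(mask_paths)))
    if (tolower(names(behavior)[1]) == "participant_id") {
      ids <- as.character(behavior[[1]])
      behavior <- behavior[, -1, drop = FALSE]
    }
  }
  lesion_cohort(ref, masks, ids = ids, behavior = behavior)
}

#' Subset a lesion cohort by participant
#'
#' @param x a `lesion_cohort`.
#' @param i integer or logical participant index.
#' @param ... ignored.
#' @export
`[.lesion_cohort` <- function(x, i, ...) {
  structure(list(geometry = x$geometry, ids = x$ids[i], masks = x$masks[i],
                 sizes_cc = x$sizes_cc[i],
                 behavior = if (is.null(x$behavior)) NULL else
                   x$behavior[i, , drop = FALSE]),
            class = "lesion_cohort")
}

#' Build the analysis mask from lesion frequency
#'
#' A voxel enters the analysis only if at least a minimum proportion of the
#' cohort has a lesion there (default 10%): voxels lesioned in too few
#' participants carry no usable statistical contrast.
#'
#' @param cohort a [lesion_cohort()].
#' @param min_frequency inclusion threshold as a proportion in `(0, 1]`.
#' @return An `analysis_mask`: sorted unique in-mask voxel indices, the
#'   threshold used, and the per-voxel lesion counts.
#' @export
build_analysis_mask <- function(cohort, min_frequency = 0.10) {
  stopifnot(inherits(cohort, "lesion_cohort"),
            min_frequency > 0, min_frequency <= 1)
  n <- length(cohort$masks)
  counts <- tabulate(unlist(cohort$masks), nbins = n_voxels(cohort$geometry))
  keep <- which(counts / n >= min_frequency - 1e-12)
  if (length(keep) == 0) stop("no voxels meet frequency threshold")
  structure(list(voxels = as.integer(keep), min_frequency = min_frequency,
                 counts = counts[keep], n = n, geometry = cohort$geometry),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> %d voxels at frequency >= %.0f%% of n = %d\n",
              length(x$voxels), 100 * x$min_frequency, x$n))
  invisible(x)
}

#' dTLVC-normalize a lesion cohort into a participants x voxels matrix
#'
#' Direct total lesion volume control: within the analysis mask, a damaged
#' voxel of participant i carries the value `1/sqrt(V_i)` where `V_i` is
#' that participant's total lesioned-voxel count (the whole lesion, not just
#' its in-mask part), and intact voxels carry 0. Voxels from smaller lesions
#' are thereby weighted more than voxels from larger lesions, controlling
#' lesion size at the voxel level.
#'
#' @param cohort a [lesion_cohort()].
#' @param mask an [build_analysis_mask()] result from this cohort.
#' @return A `dtlvc_matrix`: `values` (n x p matrix), `mask`, and
#'   `lesion_voxels` (the per-participant `V_i`).
#' @export
dtlvc_normalize <- function(cohort, mask) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(mask, "analysis_mask"))
  n <- length(cohort$masks)
  p <- length(mask$voxels)
  nv <- n_voxels(cohort$geometry)
  X <- matrix(0, n, p, dimnames = list(cohort$ids, NULL))
  Vi <- vapply(cohort$masks, length, 1L)
  hit <- logical(nv)
  for (i in seq_len(n)) {
    hit[cohort$masks[[i]]] <- TRUE
    X[i, ] <- hit[mask$voxels] / sqrt(Vi[i])
    hit[cohort$masks[[i]]] <- FALSE
  }
  structure(list(values = X, mask = mask, lesion_voxels = Vi),
            class = "dtlvc_matrix")
}

# Coerce a dtlvc_matrix (or plain matrix) to its numeric values.
lesion_values <- function(X) {
  if (inherits(X, "dtlvc_matrix")) X$values else as.matrix(X)
}

lesion_mask_of <- function(X) {
  if (inherits(X, "dtlvc_matrix")) X$mask else NULL
}

#' Voxelwise lesion frequency map
#'
#' @param cohort a [lesion_cohort()].
#' @return A 3D array in the cohort geometry; each voxel holds the fraction
#'   of participants lesioned there (range `[0, 1]`).
#' @export
lesion_frequency_map <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"), length(cohort$masks) >= 1)
  counts <- tabulate(unlist(cohort$masks), nbins = n_voxels(cohort$geometry))
  array(counts / length(cohort$masks), dim = cohort$geometry$dims)
}

#' Summarize a template's overlap with a parcellation
#'
#' For each labelled region, the percentage covered by the template (or,
#' with `denominator = "template"`, the percentage of the template falling
#' in the region). Regions with zero overlap are omitted.
#'
#' @param template a template (from [vlsm_template()]/[sccan_template()]) or
#'   an integer vector of voxel indices.
#' @param parcellation 3D integer array (0 = background) or a NIfTI path.
#' @param denominator `"region"` (default) or `"template"`.
#' @return data frame with `region_id`, `region_voxels`, `overlap_voxels`,
#'   `percent`, ordered by region id.
#' @export
region_overlap_summary <- function(template, parcellation,
                                   denominator = c("region", "template")) {
  denominator <- match.arg(denominator)
  if (is.character(parcellation))
    parcellation <- as.array(RNifti::readNifti(parcellation))
  lab <- as.integer(round(as.numeric(parcellation)))
  if (all(lab == 0)) stop("parcellation volume is all zero")
  tv <- voxel_ids(template)
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(r) {
    region <- which(lab == r)
    ov <- length(intersect(tv, region))
    if (ov == 0) return(NULL)
    denom <- if (denominator == "region") length(region) else length(tv)
    data.frame(region_id = r, region_voxels = length(region),
               overlap_voxels = ov, percent = 100 * ov / denom)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = integer(), region_voxels = integer(),
                      overlap_voxels = integer(), percent = numeric())
  out
}

#' Write a volume to NIfTI in a cohort's geometry
#'
#' @param x 3D array, or an integer vector of voxel indices (written as a
#'   binary volume).
#' @param geometry a [volume_geometry()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, geometry, path) {
  if (!is.array(x)) {
    v <- numeric(n_voxels(geometry))
    v[voxel_ids(x)] <- 1
    x <- array(v, dim = geometry$dims)
  }
  img <- RNifti::asNifti(x, reference = NULL)
  img <- RNifti::`pixdim<-`(img, geometry$voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}
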