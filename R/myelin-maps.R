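#' T1w/T2w ratio volume container
#'
#' @param values Numeric array of ratio values.
#' @param mask Logical array (same dimensions) of valid voxels.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param space Template space tag (e.g. `"MNI"`, `"NMT"`).
#' @return An object of class `ratio_volume`.
#' @export
ratio_volume <- function(values, mask, voxel_size = 1, space = "template") {
  stopifnot(is.array(values), is.array(mask) || is.logical(mask))
  mask <- array(as.logical(mask), dim(values))
  if (!identical(dim(values), dim(mask))) {
    stop("`values` and `mask` dimensions differ", call. = FALSE)
  }
  v <- values[mask]
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("in-mask ratio values must be finite and > 0", call. = FALSE)
  }
  structure(list(values = values, mask = mask,
                 voxel_size = voxel_size, space = space),
            class = "ratio_volume")
}

#' Compute the T1w/T2w ratio volume
#'
#' Divides the T1-weighted by the co-registered T2-weighted volume inside a
#' mask. The division cancels the receive-coil sensitivity profile and
#' enhances myelin contrast; the resulting units are arbitrary. In-mask
#' voxels whose T2w intensity falls at or below `t2w_floor` are a hard
#' error (they would blow up the division) and are reported by count.
#'
#' @param t1w,t2w Numeric arrays on the same grid.
#' @param mask Logical array of voxels to compute.
#' @param t2w_floor Minimum admissible in-mask T2w intensity (native units).
#' @param voxel_size,space Grid metadata forwarded to [ratio_volume()].
#' @return A [ratio_volume()]; values outside the mask are `NA`.
#' @export
compute_ratio <- function(t1w, t2w, mask, t2w_floor = 1e-6,
                          voxel_size = 1, space = "template") {
  if (!identical(dim(t1w), dim(t2w)) || !identical(dim(t1w), dim(mask))) {
    stop("`t1w`, `t2w` and `mask` must share one voxel grid", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim(t1w))
  bad <- sum(t2w[mask] <= t2w_floor, na.rm = TRUE) + sum(is.na(t2w[mask]))
  if (bad > 0) {
    stop(sprintf("%d in-mask T2w voxel(s) at or below the floor %g", bad, t2w_floor),
         call. = FALSE)
  }
  values <- array(NA_real_, dim(t1w))
  values[mask] <- t1w[mask] / t2w[mask]
  ratio_volume(values, mask, voxel_size = voxel_size, space = space)
}

#' Two-point calibration references
#'
#' Reference-structure means used to calibrate individual ratio maps to the
#' group: a low-intensity structure (ventricles) and a high-intensity one
#' (corpus callosum for humans, pons for macaques).
#'
#' @param subject_low_mean,subject_high_mean This subject's ROI means.
#' @param group_low_mean,group_high_mean Group-averaged ROI means.
#' @param ref_low_label,ref_high_label Structure names (metadata only).
#' @return An object of class `calibration_refs`.
#' @export
calibration_refs <- function(subject_low_mean, subject_high_mean,
                             group_low_mean, group_high_mean,
                             ref_low_label = "ventricles",
                             ref_high_label = "corpus_callosum") {
  stopifnot(is_scalar_num(subject_low_mean), is_scalar_num(subject_high_mean),
            is_scalar_num(group_low_mean), is_scalar_num(group_high_mean))
  if (subject_high_mean == subject_low_mean) {
    stop("degenerate references: subject high and low ROI means are equal",
         call. = FALSE)
  }
  if (group_high_mean <= group_low_mean) {
    stop("group high ROI mean must exceed the low ROI mean", call. = FALSE)
  }
  structure(list(subject_low_mean = subject_low_mean,
                 subject_high_mean = subject_high_mean,
                 group_low_mean = group_low_mean,
                 group_high_mean = group_high_mean,
                 ref_low_label = ref_low_label,
                 ref_high_label = ref_high_label),
            class = "calibration_refs")
}

#' Extract calibration references from labeled ROIs
#'
#' @param ratio A [ratio_volume()].
#' @param labels Integer array of structure labels on the same grid.
#' @param low_label,high_label Label values of the reference structures.
#' @param group_low_mean,group_high_mean Group-averaged reference values.
#' @param stat ROI summary statistic, `"mean"` (default) or `"median"`.
#' @inheritParams calibration_refs
#' @return A [calibration_refs()].
#' @export
calibration_refs_from_rois <- function(ratio, labels, low_label, high_label,
                                       group_low_mean, group_high_mean,
                                       stat = c("mean", "median"),
                                       ref_low_label = "ventricles",
                                       ref_high_label = "corpus_callosum") {
  stopifnot(inherits(ratio, "ratio_volume"))
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  lo <- ratio$values[labels == low_label & ratio$mask]
  hi <- ratio$values[labels == high_label & ratio$mask]
  if (!length(lo) || !length(hi)) {
    stop("reference ROI has no in-mask voxels", call. = FALSE)
  }
  calibration_refs(f(lo), f(hi), group_low_mean, group_high_mean,
                   ref_low_label, ref_high_label)
}

#' Calibrate a ratio volume against group reference structures
#'
#' Applies the two-point affine map `f(x) = a x + b` with
#' `a = (group_high - group_low) / (subject_high - subject_low)` and
#' `b = group_low - a * subject_low`, so the subject's own low- and
#' high-reference ROI means land exactly on the group-averaged values.
#'
#' @param ratio A [ratio_volume()].
#' @param refs A [calibration_refs()].
#' @return A calibrated [ratio_volume()].
#' @export
calibrate_ratio <- function(ratio, refs) {
  stopifnot(inherits(ratio, "ratio_volume"), inherits(refs, "calibration_refs"))
  a <- (refs$group_high_mean - refs$group_low_mean) /
       (refs$subject_high_mean - refs$subject_low_mean)
  b <- refs$group_low_mean - a * refs$subject_low_mean
  values <- ratio$values
  values[ratio$mask] <- a * values[ratio$mask] + b
  ratio_volume(values, ratio$mask, voxel_size = ratio$voxel_size,
               space = ratio$space)
}

#' Equivolume depth fraction for a linearly tapering column
#'
#' For a cortical column whose cross-sectional area varies linearly from
#' `A_w` (white/inner surface) to `A_p` (pial/outer surface), returns the
#' normalized geometric depth `rho` at which the cumulative tissue volume
#' below equals fraction `alpha` of the column volume:
#' \deqn{\rho(\alpha) = \frac{-A_w + \sqrt{(1-\alpha) A_w^2 + \alpha A_p^2}}{A_p - A_w},}
#' reducing to `rho = alpha` when `A_p = A_w`. This is the equi-volume
#' placement rule that compensates cortical curvature: bins are thinner
#' where the bounding area is larger.
#'
#' @param A_w,A_p Inner and outer bounding areas, mm^2 (`> 0`).
#' @param alpha Cumulative volume fraction(s) in `[0, 1]`.
#' @return Depth fraction(s) `rho` in `[0, 1]`.
#' @examples
#' equivolume_rho(1, 2, 0.5)  # sqrt(2.5) - 1
#' @export
equivolume_rho <- function(A_w, A_p, alpha) {
  stopifnot(is.numeric(A_w), is.numeric(A_p), is.numeric(alpha))
  if (any(A_w <= 0) || any(A_p <= 0)) stop("areas must be > 0", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  n <- max(length(A_w), length(A_p), length(alpha))
  A_w <- rep_len(A_w, n); A_p <- rep_len(A_p, n); alpha <- rep_len(alpha, n)
  flat <- abs(A_p - A_w) < 1e-12 * pmax(A_w, A_p)
  rho <- alpha
  if (any(!flat)) {
    i <- !flat
    rho[i] <- (-A_w[i] + sqrt((1 - alpha[i]) * A_w[i]^2 + alpha[i] * A_p[i]^2)) /
      (A_p[i] - A_w[i])
  }
  pmin(pmax(rho, 0), 1)
}

#' Cumulative volume fraction at a geometric depth (inverse of equivolume_rho)
#'
#' @inheritParams equivolume_rho
#' @param rho Normalized geometric depth(s) in `[0, 1]`, 0 = white surface.
#' @return Volume fraction(s) `alpha` in `[0, 1]`.
#' @export
equivolume_alpha <- function(A_w, A_p, rho) {
  stopifnot(is.numeric(A_w), is.numeric(A_p), is.numeric(rho))
  if (any(A_w <= 0) || any(A_p <= 0)) stop("areas must be > 0", call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("`rho` must lie in [0, 1]", call. = FALSE)
  (2 * A_w * rho + (A_p - A_w) * rho^2) / (A_w + A_p)
}

#' Assign equivolumetric depth bins
#'
#' Labels each ribbon voxel with its depth bin `k` in `1..K` (bin 1 =
#' deepest, adjacent to white matter), where voxel volume fraction
#' `alpha` falls in `[(k-1)/K, k/K)` (`alpha = 1` goes to bin K). Accepts
#' either a [make_phantom_ribbon()] object (alpha computed analytically
#' from the geometry) or a precomputed alpha array plus ribbon mask.
#'
#' @param x A `phantom_ribbon`, or a numeric array of per-voxel cumulative
#'   volume fractions (`NA` outside the ribbon).
#' @param K Number of bins.
#' @param ribbon_mask Logical array of ribbon voxels; required when `x` is
#'   an alpha array.
#' @return Integer array of bin labels, 0 outside the ribbon.
#' @export
assign_depth_bins <- function(x, K, ribbon_mask = NULL) {
  stopifnot(is_scalar_num(K), K >= 1)
  K <- as.integer(K)
  if (inherits(x, "phantom_ribbon")) {
    alpha <- ribbon_alpha(x)
    ribbon_mask <- x$labels == 1L
  } else {
    alpha <- x
    if (is.null(ribbon_mask)) ribbon_mask <- !is.na(alpha)
    ribbon_mask <- array(as.logical(ribbon_mask), dim(alpha))
  }
  if (any(ribbon_mask & is.na(alpha))) {
    stop(sprintf("%d ribbon voxel(s) lack a depth coordinate",
                 sum(ribbon_mask & is.na(alpha))), call. = FALSE)
  }
  a <- alpha[ribbon_mask]
  if (any(a < 0 | a > 1)) stop("alpha outside [0, 1] inside ribbon", call. = FALSE)
  bins <- array(0L, dim(alpha))
  bins[ribbon_mask] <- pmin(floor(a * K), K - 1L) + 1L
  bins
}

#' Depth bins from a geometric depth coordinate via the equivolume transform
#'
#' Converts a normalized geometric depth field `rho` (0 at the white
#' surface, 1 at the pial surface) to volume fractions with
#' [equivolume_alpha()] under per-voxel (or global) bounding areas, then
#' bins with [assign_depth_bins()].
#'
#' @param rho Numeric array of geometric depths, `NA` outside the ribbon.
#' @param A_w,A_p Bounding areas (scalars or arrays conformable with `rho`).
#' @param K Number of bins.
#' @return Integer bin-label array, 0 outside the ribbon.
#' @export
depth_bins_from_rho <- function(rho, A_w, A_p, K) {
  mask <- !is.na(rho)
  alpha <- rho
  aw <- if (length(A_w) == 1) rep_len(A_w, sum(mask)) else A_w[mask]
  ap <- if (length(A_p) == 1) rep_len(A_p, sum(mask)) else A_p[mask]
  alpha[mask] <- equivolume_alpha(aw, ap, rho[mask])
  assign_depth_bins(alpha, K, ribbon_mask = mask)
}

#' Drop the outermost depth bins
#'
#' Removes bins 1 and K (the bins abutting white matter and the brain
#' surface, most exposed to partial-volume contamination) and relabels the
#' survivors `1..(K-2)`, so a 7-bin segmentation yields the 5 analysis bins.
#'
#' @param bins Integer bin-label array from [assign_depth_bins()].
#' @param K The bin count used to build `bins`.
#' @return Relabeled integer array; dropped voxels become 0.
#' @export
trim_extreme_bins <- function(bins, K) {
  stopifnot(K >= 3)
  out <- bins
  out[bins == 1L | bins == as.integer(K)] <- 0L
  keep <- out > 0L
  out[keep] <- out[keep] - 1L
  out
}

#' Extract parcel x depth-bin ratio profiles
#'
#' Averages in-mask ratio values over every (parcel, depth bin) cell.
#' Empty cells are kept as explicit rows with `n_voxels = 0` and `NA` mean
#' (and reported via a warning) rather than silently dropped.
#'
#' @param ratio A [ratio_volume()].
#' @param bins Integer bin-label array (0 outside the ribbon).
#' @param parcels Integer parcel-label array (0 = unlabeled).
#' @param trim_extremes If `TRUE`, apply [trim_extreme_bins()] first.
#' @param K Bin count in `bins` (needed for trimming and for enumerating
#'   empty cells); inferred from `bins` when missing.
#' @param subject_id Identifier written into the output rows.
#' @return Data frame `subject_id, parcel, depth_bin, mean_ratio, n_voxels`.
#' @export
extract_depth_profiles <- function(ratio, bins, parcels, trim_extremes = FALSE,
                                   K = NULL, subject_id = "subject") {
  stopifnot(inherits(ratio, "ratio_volume"))
  if (!identical(dim(ratio$values), dim(bins)) ||
      !identical(dim(ratio$values), dim(parcels))) {
    stop("`ratio`, `bins` and `parcels` must share one voxel grid", call. = FALSE)
  }
  if (is.null(K)) K <- max(bins)
  if (trim_extremes) {
    bins <- trim_extreme_bins(bins, K)
    K <- K - 2L
  }
  use <- ratio$mask & bins > 0L & parcels > 0L
  parcel_ids <- sort(unique(parcels[parcels > 0L]))
  cells <- expand.grid(depth_bin = seq_len(K), parcel = parcel_ids)
  key <- interaction(factor(parcels[use], levels = parcel_ids),
                     factor(bins[use], levels = seq_len(K)), drop = FALSE)
  sums <- tapply(ratio$values[use], key, sum)
  ns <- tapply(ratio$values[use], key, length)
  cell_key <- paste(cells$parcel, cells$depth_bin, sep = ".")
  n_voxels <- as.integer(ns[cell_key])
  n_voxels[is.na(n_voxels)] <- 0L
  mean_ratio <- as.numeric(sums[cell_key]) / n_voxels
  mean_ratio[n_voxels == 0L] <- NA_real_
  out <- data.frame(subject_id = subject_id, parcel = cells$parcel,
                    depth_bin = cells$depth_bin, mean_ratio = mean_ratio,
                    n_voxels = n_voxels, stringsAsFactors = FALSE)
  out <- out[order(out$parcel, out$depth_bin), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$n_voxels == 0L)) {
    warning(sprintf("%d empty (parcel, bin) cell(s) reported with n_voxels = 0",
                    sum(out$n_voxels == 0L)), call. = FALSE)
  }
  out
}

#' Write / read a ratio volume as NIfTI
#'
#' @param ratio A [ratio_volume()].
#' @param path Output path (`.nii` / `.nii.gz`).
#' @return `path` invisibly (write) or a [ratio_volume()] (read).
#' @export
write_ratio_nifti <- function(ratio, path) {
  stopifnot(inherits(ratio, "ratio_volume"))
  img <- RNifti::asNifti(ratio$values, internal = FALSE)
  RNifti::pixdim(img) <- rep(ratio$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ratio_nifti
#' @param space Template tag attached on read.
#' @export
read_ratio_nifti <- function(path, space = "template") {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim(img))
  mask <- is.finite(values) & values > 0
  values[!mask] <- NA_real_
  ratio_volume(values, mask, voxel_size = RNifti::pixdim(img)[1], space = space)
}
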