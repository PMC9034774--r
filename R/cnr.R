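#' Reference-region statistics
#'
#' Mean and standard deviation (n-1 denominator) of voxel intensities within
#' a reference mask, typically a region in the central pons. These anchor
#' the contrast-to-noise ratio of [cnr_map()].
#'
#' @param volume 3-d numeric array of intensities.
#' @param ref_mask logical/0-1 array of the same shape.
#' @return list of class `reference_stats` with `mean_ref`, `sd_ref`,
#'   `n_voxels`.
#' @export
reference_stats <- function(volume, ref_mask) {
  check_congruent(volume, ref_mask)
  v <- volume[ref_mask > 0]
  if (length(v) < 2) stop("reference mask must contain at least 2 voxels", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("reference region has zero intensity SD", call. = FALSE)
  structure(list(mean_ref = mean(v), sd_ref = s, n_voxels = length(v)),
            class = "reference_stats")
}

#' Voxelwise contrast-to-noise ratio map
#'
#' CNR of every voxel `v` against the reference region:
#' \deqn{CNR = (v - Mean_{REF}) / SD_{REF}.}
#' The map is invariant to affine intensity transforms `v -> a v + b`
#' (a > 0) applied jointly to the volume and the reference.
#'
#' @param volume 3-d intensity array.
#' @param stats a [reference_stats()] object.
#' @return 3-d array of CNR values.
#' @export
cnr_map <- function(volume, stats) {
  stopifnot(inherits(stats, "reference_stats"))
  (volume - stats$mean_ref) / stats$sd_ref
}

#' Threshold-based locus coeruleus segmentation
#'
#' Marks voxels whose intensity exceeds the reference mean by more than
#' `k` reference SDs (strictly greater), i.e. voxels with CNR > `k`,
#' restricted to a candidate search mask. The default `k = 5` is the
#' conventional segmentation threshold for neuromelanin-sensitive
#' contrast. An empty result is allowed.
#'
#' @param volume 3-d intensity array.
#' @param stats [reference_stats()].
#' @param k threshold in reference SD units (default 5).
#' @param candidate_mask logical array restricting the search (default:
#'   whole volume).
#' @return logical array mask.
#' @export
segment_lc <- function(volume, stats, k = 5, candidate_mask = NULL) {
  stopifnot(inherits(stats, "reference_stats"))
  if (is.null(candidate_mask)) candidate_mask <- array(TRUE, dim(volume))
  check_congruent(volume, candidate_mask)
  (volume > stats$mean_ref + k * stats$sd_ref) & (candidate_mask > 0)
}

#' Build a probabilistic atlas from binary masks
#'
#' Voxelwise mean of individual binary masks: each voxel's value is the
#' proportion of masks in which it appears, i.e. the probability of being
#' identified as locus coeruleus at the population level.
#'
#' @param masks list of congruent logical/0-1 arrays (>= 1).
#' @return 3-d array of probabilities in `[0, 1]`.
#' @export
build_atlas <- function(masks) {
  if (!length(masks)) stop("need at least one mask", call. = FALSE)
  d <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), d)) stop("mask shapes differ", call. = FALSE)
  }
  Reduce(`+`, lapply(masks, function(m) (m > 0) * 1)) / length(masks)
}

#' Threshold a probabilistic atlas
#'
#' Retains voxels whose atlas probability is at least `p` (inclusive
#' comparison). Typical thresholds are 0.05 (sensitive) and 0.25
#' (conservative); the 0.25 mask is always a subset of the 0.05 mask.
#'
#' @param atlas probability array from [build_atlas()].
#' @param p threshold in (0, 1).
#' @return logical array mask.
#' @export
threshold_atlas <- function(atlas, p) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  atlas >= p
}

#' Split a locus coeruleus mask into caudal/middle/rostral thirds
#'
#' The z slices intersecting the mask (z increasing inferior to superior)
#' are split into three contiguous groups with equal slice counts; when the
#' occupied slice count is not divisible by three, the extra slices go to
#' the middle subregion first, then the rostral. Caudal is the most
#' inferior group, rostral the most superior. The outputs partition the
#' input mask.
#'
#' @param mask logical 3-d array, nonempty, occupying >= 3 z slices.
#' @return named list of three logical arrays: `caudal`, `middle`,
#'   `rostral`.
#' @export
split_subregions <- function(mask) {
  occ <- which(apply(mask > 0, 3, any))
  if (length(occ) < 3) stop("mask must occupy at least 3 z slices", call. = FALSE)
  nz <- length(occ)
  base <- nz %/% 3
  rem <- nz %% 3
  counts <- c(caudal = base, middle = base + (rem >= 1), rostral = base + (rem >= 2))
  idx <- split(occ, rep(names(counts), times = counts) |>
                 factor(levels = names(counts)))
  out <- lapply(idx, function(zs) {
    m <- array(FALSE, dim(mask))
    m[, , zs] <- mask[, , zs] > 0
    m
  })
  names(out) <- names(counts)
  out
}

#' Extract CNR and SNR summaries for the locus coeruleus
#'
#' Mean CNR over the whole (bilateral, pooled-voxel) locus coeruleus mask
#' and over each subregion, plus a per-subregion signal-to-noise ratio.
#' SNR here is a declared convention (the mean raw intensity within the
#' subregion divided by the reference SD); it is reported alongside CNR to
#' allow subregion comparisons. Empty subregions yield `NA`, never zero.
#'
#' @param cnr 3-d CNR array from [cnr_map()].
#' @param lc_mask logical array: the (bilateral) thresholded atlas mask.
#' @param subregions list from [split_subregions()] (computed from
#'   `lc_mask` when omitted).
#' @param volume raw intensity array (for SNR).
#' @param stats [reference_stats()].
#' @param atlas_threshold the probability threshold used to make `lc_mask`
#'   (recorded in the output).
#' @return one-row tibble of class `cnr_summary`: `cnr_whole`,
#'   `cnr_rostral`, `cnr_middle`, `cnr_caudal`, `snr_rostral`, `snr_middle`,
#'   `snr_caudal`, `n_voxels`, `atlas_threshold`.
#' @export
extract_summary <- function(cnr, lc_mask, subregions = NULL, volume = NULL,
                            stats = NULL, atlas_threshold = NA_real_) {
  check_congruent(cnr, lc_mask)
  if (!any(lc_mask > 0)) stop("empty locus coeruleus mask", call. = FALSE)
  if (is.null(subregions)) subregions <- split_subregions(lc_mask)
  mean_in <- function(arr, m) if (any(m > 0)) mean(arr[m > 0]) else NA_real_
  snr_in <- function(m) {
    if (is.null(volume) || is.null(stats)) return(NA_real_)
    if (!any(m > 0)) return(NA_real_)
    mean(volume[m > 0]) / stats$sd_ref
  }
  out <- tibble::tibble(
    cnr_whole = mean_in(cnr, lc_mask),
    cnr_rostral = mean_in(cnr, subregions$rostral),
    cnr_middle = mean_in(cnr, subregions$middle),
    cnr_caudal = mean_in(cnr, subregions$caudal),
    snr_rostral = snr_in(subregions$rostral),
    snr_middle = snr_in(subregions$middle),
    snr_caudal = snr_in(subregions$caudal),
    n_voxels = sum(lc_mask > 0),
    atlas_threshold = atlas_threshold
  )
  class(out) <- c("cnr_summary", class(out))
  out
}

check_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("arrays are not congruent", call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI volume asserting the z-axis convention
#'
#' Loads a NIfTI image and checks from its orientation metadata that the
#' third array axis increases from inferior to superior (an orientation
#' string ending in "S", e.g. "RAS" or "LAS"), which the subregion split
#' relies on. An undetermined or non-superior z axis is an explicit error.
#'
#' @param path NIfTI file.
#' @return list with `data` (3-d array), `pixdim` (voxel sizes, mm) and
#'   `orientation`.
#' @export
read_oriented_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.na(orient) || nchar(orient) != 3 || substr(orient, 3, 3) != "S") {
    stop("cannot confirm an inferior-to-superior z axis (orientation '",
         orient, "'); reorient the image first", call. = FALSE)
  }
  list(data = as.array(img), pixdim = RNifti::pixdim(img), orientation = orient)
}

#' Write a 3-d array as NIfTI
#'
#' @param data 3-d array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes in mm (length 3).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(data, path, pixdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(data * 1)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}
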