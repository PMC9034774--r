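#' Brainstem phantom specification
#'
#' Geometry and intensity structure of a synthetic magnetization-transfer
#' volume used to test the contrast-to-noise extraction with known ground
#' truth: two ellipsoidal locus coeruleus regions (one per hemisphere), a
#' cuboidal pontine reference region, and per-subregion intensity offsets
#' expressed in multiples of the reference SD (so the true subregion CNR
#' equals the configured offset by construction). Voxel intensities are the
#' reference mean plus additive Gaussian noise plus the offsets inside the
#' locus coeruleus.
#'
#' The z extent of the ellipsoids must divide into the three equal-slice
#' subregions (caudal/middle/rostral, inferior to superior).
#'
#' @param shape integer 3-vector of grid dimensions (x, y, z).
#' @param voxel_mm voxel size in mm (length 3).
#' @param lc_centers list of two numeric 3-vectors: ellipsoid centres
#'   (voxel coordinates) of the left and right locus coeruleus.
#' @param lc_radii numeric 3-vector of ellipsoid radii in voxels (shared).
#' @param ref_bounds list with `x`, `y`, `z` integer ranges (each length 2)
#'   of the reference cuboid.
#' @param offsets named numeric vector `c(caudal=, middle=, rostral=)`:
#'   intensity offsets in multiples of `ref_sd`.
#' @param ref_mean,ref_sd reference-region mean intensity and the SD unit
#'   in which the offsets are expressed. For a self-consistent noisy
#'   phantom (configured offsets = true CNR) set `ref_sd = noise_sd`.
#' @param noise_sd additive Gaussian noise SD (0 for a noiseless phantom).
#' @param seed integer seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 30), voxel_mm = c(0.5, 0.5, 0.5),
                         lc_centers = list(c(18, 24, 19), c(31, 24, 19)),
                         lc_radii = c(2.5, 2.5, 9),
                         ref_bounds = list(x = c(20, 29), y = c(6, 13), z = c(12, 26)),
                         offsets = c(caudal = 4, middle = 5, rostral = 6),
                         ref_mean = 100, ref_sd = 5, noise_sd = 5, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 1), all(voxel_mm > 0),
            length(lc_centers) == 2, length(lc_radii) == 3,
            all(c("caudal", "middle", "rostral") %in% names(offsets)),
            ref_sd > 0, noise_sd >= 0)
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 lc_centers = lc_centers, lc_radii = lc_radii,
                 ref_bounds = ref_bounds, offsets = offsets,
                 ref_mean = ref_mean, ref_sd = ref_sd, noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, center, radii) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  dx <- ((x - center[1]) / radii[1])^2
  dy <- ((y - center[2]) / radii[2])^2
  dz <- ((z - center[3]) / radii[3])^2
  outer(outer(dx, dy, `+`), dz, `+`) <= 1
}

cuboid_mask <- function(shape, bounds) {
  m <- array(FALSE, shape)
  m[bounds$x[1]:bounds$x[2], bounds$y[1]:bounds$y[2], bounds$z[1]:bounds$z[2]] <- TRUE
  m
}

#' Generate a brainstem phantom volume with known CNR ground truth
#'
#' Builds the intensity volume described by a [phantom_spec()]: reference
#' mean everywhere, additive Gaussian noise, and per-subregion offsets
#' (in units of the configured reference SD) inside the locus coeruleus
#' ellipsoids. Subregion membership is assigned by splitting the occupied
#' locus coeruleus z slices into equal thirds. With zero noise the mean CNR
#' of each subregion equals its configured offset exactly.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (3-d array), `lc_left`, `lc_right`,
#'   `lc_mask` (their union), `ref_mask`, `subregions` (list of three
#'   masks) and `truth` (tibble of configured subregion CNR offsets).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  lc_left <- ellipsoid_mask(shape, spec$lc_centers[[1]], spec$lc_radii)
  lc_right <- ellipsoid_mask(shape, spec$lc_centers[[2]], spec$lc_radii)
  lc <- lc_left | lc_right
  ref <- cuboid_mask(shape, spec$ref_bounds)
  if (any(lc & ref)) stop("locus coeruleus and reference regions overlap", call. = FALSE)
  sub <- split_subregions(lc)
  vol <- with_local_seed(spec$seed, {
    v <- array(spec$ref_mean, shape)
    if (spec$noise_sd > 0) {
      v <- v + array(stats::rnorm(prod(shape), 0, spec$noise_sd), shape)
    }
    for (nm in c("caudal", "middle", "rostral")) {
      v[sub[[nm]]] <- v[sub[[nm]]] + spec$offsets[[nm]] * spec$ref_sd
    }
    v
  })
  truth <- tibble::tibble(
    subregion = c("caudal", "middle", "rostral"),
    true_cnr = as.numeric(spec$offsets[c("caudal", "middle", "rostral")])
  )
  list(volume = vol, lc_left = lc_left, lc_right = lc_right, lc_mask = lc,
       ref_mask = ref, subregions = sub, truth = truth, spec = spec)
}
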