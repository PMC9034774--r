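test_that("reference statistics use the n-1 standard deviation", {
  vol <- array(0, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4))
  mask[1:2, 1, 1] <- TRUE
  vol[1:2, 1, 1] <- c(10, 12)
  st <- reference_stats(vol, mask)
  expect_equal(st$mean_ref, 11)
  expect_equal(st$sd_ref, sqrt(2))
  expect_equal(st$n_voxels, 2L)
  vol[1:2, 1, 1] <- c(7, 7)
  expect_error(reference_stats(vol, mask), "SD")
  expect_error(reference_stats(vol, array(FALSE, c(4, 4, 4))), "2 voxels")
})

test_that("reference statistics match a two-pass manual computation", {
  withr::with_seed(61, {
    vol <- array(rnorm(10 * 10 * 10, 100, 5), c(10, 10, 10))
  })
  mask <- array(TRUE, c(10, 10, 10))
  st <- reference_stats(vol, mask)
  v <- as.vector(vol)
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  expect_equal(st$mean_ref, m, tolerance = 1e-10)
  expect_equal(st$sd_ref, s, tolerance = 1e-10)
})

test_that("the CNR map is the standardized signal difference", {
  ph <- make_phantom(phantom_spec(noise_sd = 0))
  st <- structure(list(mean_ref = 100, sd_ref = 5, n_voxels = 100L),
                  class = "reference_stats")
  cn <- cnr_map(ph$volume, st)
  expect_equal(cn[!ph$lc_mask & !ph$ref_mask][1], 0)
  vol2 <- ph$volume
  vol2[1, 1, 1] <- st$mean_ref + 5 * st$sd_ref
  expect_equal(cnr_map(vol2, st)[1, 1, 1], 5)
})

test_that("CNR is invariant to affine intensity transforms", {
  ph <- make_phantom(phantom_spec(noise_sd = 4, seed = 62))
  st <- reference_stats(ph$volume, ph$ref_mask)
  cn <- cnr_map(ph$volume, st)
  for (ab in list(c(2.5, 10), c(0.3, -40))) {
    vol2 <- ab[1] * ph$volume + ab[2]
    st2 <- reference_stats(vol2, ph$ref_mask)
    expect_lt(max(abs(cnr_map(vol2, st2) - cn)), 1e-12)
  }
})

test_that("threshold segmentation captures voxels beyond k reference SDs", {
  spec <- phantom_spec(noise_sd = 0, offsets = c(caudal = 6, middle = 6, rostral = 6))
  ph <- make_phantom(spec)
  st <- list(mean_ref = spec$ref_mean, sd_ref = spec$ref_sd, n_voxels = 100L)
  class(st) <- "reference_stats"
  seg <- segment_lc(ph$volume, st)
  expect_true(all(seg[ph$lc_mask]))
  expect_false(any(seg[!ph$lc_mask]))
  # offsets below the threshold yield an empty mask
  ph4 <- make_phantom(phantom_spec(noise_sd = 0,
                                   offsets = c(caudal = 4, middle = 4, rostral = 4)))
  expect_false(any(segment_lc(ph4$volume, st)))
})

test_that("noisy capture fraction matches the Gaussian tail probability", {
  spec <- phantom_spec(noise_sd = 5, offsets = c(caudal = 6, middle = 6, rostral = 6),
                       seed = 63)
  ph <- make_phantom(spec)
  st <- list(mean_ref = spec$ref_mean, sd_ref = spec$ref_sd, n_voxels = 1000L)
  class(st) <- "reference_stats"
  seg <- segment_lc(ph$volume, st, candidate_mask = ph$lc_mask)
  n_lc <- sum(ph$lc_mask)
  # voxel exceeds mean + 5 SD_ref iff its noise exceeds -1 SD_ref
  p_capture <- pnorm((6 - 5) * spec$ref_sd / spec$noise_sd)
  phat <- sum(seg) / n_lc
  expect_lt(abs(phat - p_capture), 3 * sqrt(p_capture * (1 - p_capture) / n_lc))
})

test_that("probabilistic atlas averages binary masks", {
  m1 <- array(c(TRUE, FALSE, FALSE, FALSE), c(2, 2, 1))
  m2 <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  at <- build_atlas(list(m1, m2))
  expect_equal(at[1, 1, 1], 1)
  expect_equal(at[2, 1, 1], 0.5)
  expect_equal(build_atlas(list(m1, m1))[!m1], rep(0, 3), ignore_attr = TRUE)
  one_of_four <- build_atlas(list(m1, m1 & FALSE, m1 & FALSE, m1 & FALSE))
  expect_equal(one_of_four[1, 1, 1], 0.25)
  # counting identity: atlas sum equals total voxel count over masks / n
  withr::with_seed(64, {
    masks <- lapply(1:5, function(i) array(runif(27) < 0.4, c(3, 3, 3)))
  })
  expect_equal(sum(build_atlas(masks)), sum(vapply(masks, sum, numeric(1))) / 5)
  expect_error(build_atlas(list(m1, array(TRUE, c(3, 3, 1)))), "shapes")
  expect_error(build_atlas(list()), "at least one")
})

test_that("atlas thresholding is inclusive and monotone", {
  at <- array(c(0, 0.1, 0.25, 0.6), c(4, 1, 1))
  m05 <- threshold_atlas(at, 0.05)
  m25 <- threshold_atlas(at, 0.25)
  expect_equal(sum(m05), 3)             # every positive voxel retained
  expect_equal(sum(m25), 2)             # inclusive comparison keeps 0.25
  expect_true(all(m25[m25] %in% m05[m25]))
  expect_true(all(which(m25) %in% which(m05)))
  # retained count equals a brute-force scan
  withr::with_seed(65, {
    at2 <- array(runif(1000), c(10, 10, 10))
  })
  expect_equal(sum(threshold_atlas(at2, 0.3)), sum(as.vector(at2) >= 0.3))
  expect_error(threshold_atlas(at, 0), "p must")
  expect_error(threshold_atlas(at, 1), "p must")
})

test_that("subregion split partitions occupied slices inferior to superior", {
  mk_mask <- function(zs, shape = c(4, 4, 15)) {
    m <- array(FALSE, shape)
    m[2, 2, zs] <- TRUE
    m
  }
  # 9 occupied slices: 3/3/3
  s9 <- split_subregions(mk_mask(4:12))
  expect_equal(which(apply(s9$caudal, 3, any)), 4:6)
  expect_equal(which(apply(s9$middle, 3, any)), 7:9)
  expect_equal(which(apply(s9$rostral, 3, any)), 10:12)
  # 10 slices: remainder goes to the middle first (3/4/3)
  s10 <- split_subregions(mk_mask(3:12))
  expect_equal(sum(apply(s10$caudal, 3, any)), 3)
  expect_equal(sum(apply(s10$middle, 3, any)), 4)
  expect_equal(sum(apply(s10$rostral, 3, any)), 3)
  # 11 slices: 3/4/4
  s11 <- split_subregions(mk_mask(2:12))
  expect_equal(sum(apply(s11$caudal, 3, any)), 3)
  expect_equal(sum(apply(s11$middle, 3, any)), 4)
  expect_equal(sum(apply(s11$rostral, 3, any)), 4)
  expect_error(split_subregions(mk_mask(4:5)), "3 z slices")
})

test_that("subregion masks partition the input for any occupied extent", {
  withr::with_seed(66, {
    for (nz in 3:12) {
      m <- array(FALSE, c(5, 5, 14))
      zs <- sort(sample(1:14, nz))
      for (z in zs) m[sample(1:5, 2), sample(1:5, 2), z] <- TRUE
      sub <- split_subregions(m)
      un <- sub$caudal | sub$middle | sub$rostral
      expect_identical(un, m)
      expect_false(any(sub$caudal & sub$middle))
      expect_false(any(sub$middle & sub$rostral))
      expect_false(any(sub$caudal & sub$rostral))
      counts <- vapply(sub, function(s) sum(apply(s, 3, any)), numeric(1))
      expect_lte(max(counts) - min(counts), 1)
    }
  })
})

test_that("summary extraction recovers noiseless subregion offsets exactly", {
  ph <- make_phantom(phantom_spec(noise_sd = 0))
  st <- list(mean_ref = 100, sd_ref = 5, n_voxels = 100L)
  class(st) <- "reference_stats"
  cn <- cnr_map(ph$volume, st)
  summ <- extract_summary(cn, ph$lc_mask, ph$subregions, ph$volume, st,
                          atlas_threshold = 0.05)
  expect_equal(summ$cnr_rostral, 6)
  expect_equal(summ$cnr_middle, 5)
  expect_equal(summ$cnr_caudal, 4)
  # pooled whole-structure mean is the voxel-count-weighted subregion mean
  w <- vapply(ph$subregions, sum, numeric(1))
  expect_equal(summ$cnr_whole,
               sum(w * c(summ$cnr_caudal, summ$cnr_middle, summ$cnr_rostral)[
                 match(names(w), c("caudal", "middle", "rostral"))]) / sum(w))
  # empty subregion is flagged missing, not zero
  empty_sub <- ph$subregions
  empty_sub$rostral <- array(FALSE, dim(ph$volume))
  s2 <- extract_summary(cn, ph$lc_mask, empty_sub, ph$volume, st)
  expect_true(is.na(s2$cnr_rostral))
  expect_error(extract_summary(cn, array(FALSE, dim(cn))), "empty")
})

test_that("noisy phantom CNR is recovered within sampling error", {
  spec <- phantom_spec(noise_sd = 5, seed = 67)
  ph <- make_phantom(spec)
  st <- reference_stats(ph$volume, ph$ref_mask)
  cn <- cnr_map(ph$volume, st)
  summ <- extract_summary(cn, ph$lc_mask, ph$subregions, ph$volume, st)
  for (sub in c("caudal", "middle", "rostral")) {
    n_vox <- sum(ph$subregions[[sub]])
    se <- (spec$noise_sd / spec$ref_sd) / sqrt(n_vox)
    expect_lt(abs(summ[[paste0("cnr_", sub)]] - spec$offsets[[sub]]), 3.5 * se)
  }
})

test_that("phantom geometry is validated", {
  bad <- phantom_spec(ref_bounds = list(x = c(15, 35), y = c(20, 30), z = c(10, 28)))
  expect_error(make_phantom(bad), "overlap")
  ph0 <- make_phantom(phantom_spec(noise_sd = 0,
                                   offsets = c(caudal = 0, middle = 0, rostral = 0)))
  st <- list(mean_ref = 100, sd_ref = 5, n_voxels = 10L)
  class(st) <- "reference_stats"
  expect_true(all(cnr_map(ph0$volume, st) == 0))
})

test_that("NIfTI round trip preserves data and asserts orientation", {
  skip_if_not_installed("RNifti")
  ph <- make_phantom(phantom_spec(shape = c(12, 12, 9), voxel_mm = c(1, 1, 1),
                                  lc_centers = list(c(4, 6, 5), c(9, 6, 5)),
                                  lc_radii = c(1.5, 1.5, 3),
                                  ref_bounds = list(x = c(5, 8), y = c(2, 3), z = c(3, 7)),
                                  noise_sd = 0))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(ph$volume, path, pixdim = c(1, 1, 1))
  back <- read_oriented_nifti(path)
  expect_equal(back$data, ph$volume, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(substr(back$orientation, 3, 3), "S")
})
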