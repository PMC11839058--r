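dims <- c(6, 6, 4)

test_that("ratio computation divides inside the mask and guards the floor", {
  t2 <- array(4, dims)
  msk <- array(TRUE, dims)
  rv <- compute_ratio(array(4, dims), t2, msk)
  expect_true(all(rv$values[rv$mask] == 1))
  rv2 <- compute_ratio(array(2, dims), t2, msk)
  expect_true(all(rv2$values[rv2$mask] == 0.5))

  t2bad <- t2; t2bad[1:3] <- 0
  expect_error(compute_ratio(array(2, dims), t2bad, msk), "3 in-mask")
  expect_error(compute_ratio(array(2, dims), array(4, c(2, 2, 2)), msk),
               "share one voxel grid")
})

test_that("two-point calibration is affine-exact on its anchors", {
  refs <- calibration_refs(0.5, 2.0, 0.6, 1.8)
  # a = (1.8 - 0.6)/(2.0 - 0.5) = 0.8, b = 0.6 - 0.8 * 0.5 = 0.2
  vals <- array(1.0, dims)
  rv <- ratio_volume(vals, array(TRUE, dims))
  cal <- calibrate_ratio(rv, refs)
  expect_equal(cal$values[1], 0.8 * 1.0 + 0.2)
  # anchors map exactly onto the group means
  vals2 <- array(c(0.5, 2.0), dims)
  cal2 <- calibrate_ratio(ratio_volume(vals2, array(TRUE, dims)), refs)
  expect_equal(sort(unique(as.vector(cal2$values))), c(0.6, 1.8))
  # identity when subject means equal group means
  refs_id <- calibration_refs(0.6, 1.8, 0.6, 1.8)
  cal3 <- calibrate_ratio(rv, refs_id)
  expect_equal(cal3$values, rv$values)
  expect_error(calibration_refs(1, 1, 0.6, 1.8), "degenerate")
})

test_that("calibration is order-preserving and commutes with permutation", {
  set.seed(1)
  vals <- array(runif(prod(dims), 0.5, 2), dims)
  rv <- ratio_volume(vals, array(TRUE, dims))
  refs <- calibration_refs(0.4, 1.9, 0.55, 1.75)
  cal <- calibrate_ratio(rv, refs)
  expect_equal(order(as.vector(vals)), order(as.vector(cal$values)))
  # per-voxel map: permuting voxels then calibrating equals calibrating then
  # permuting
  p <- sample(prod(dims))
  vp <- array(as.vector(vals)[p], dims)
  cal_p <- calibrate_ratio(ratio_volume(vp, array(TRUE, dims)), refs)
  expect_equal(as.vector(cal_p$values), as.vector(cal$values)[p])
})

test_that("equivolume depth fraction matches its closed form and limits", {
  expect_equal(equivolume_rho(1.3, 1.3, c(0, 0.25, 1)), c(0, 0.25, 1))
  expect_equal(equivolume_rho(1, 2, 0.5), sqrt(2.5) - 1, tolerance = 1e-12)
  expect_equal(equivolume_rho(0.7, 2.4, c(0, 1)), c(0, 1))
  expect_error(equivolume_rho(1, 2, 1.2), "0, 1")
})

test_that("equivolume closed form agrees with numerical inversion to 1e-9", {
  set.seed(42)
  for (i in 1:100) {
    A_w <- runif(1, 0.2, 3); A_p <- runif(1, 0.2, 3); a <- runif(1)
    num <- stats::uniroot(function(rho) {
      (2 * A_w * rho + (A_p - A_w) * rho^2) / (A_w + A_p) - a
    }, c(0, 1), tol = 1e-13)$root
    expect_equal(equivolume_rho(A_w, A_p, a), num, tolerance = 1e-9)
    expect_equal(equivolume_alpha(A_w, A_p, num), a, tolerance = 1e-9)
  }
})

test_that("slab bins are equidistant and annulus boundary is the equal-area radius", {
  slab <- make_phantom_ribbon("slab", 0, 2.4, voxel_size = 0.1,
                              grid_shape = c(10, 10, 26))
  bins <- assign_depth_bins(slab, 6)
  expect_equal(tabulate(bins[bins > 0], 6), rep(400L, 6))

  ann <- make_phantom_ribbon("annulus", 10, 12, voxel_size = 0.1,
                             grid_shape = c(280, 280, 2))
  b2 <- assign_depth_bins(ann, 2)
  al <- ribbon_alpha(ann)
  r <- sqrt(al * (144 - 100) + 100)
  # boundary radius sqrt((r_in^2 + r_out^2)/2) = sqrt(122), within one voxel
  expect_lt(max(r[b2 == 1L], na.rm = TRUE), sqrt(122) + 0.1)
  expect_gt(min(r[b2 == 2L], na.rm = TRUE), sqrt(122) - 0.1)
})

test_that("trimming a 7-bin segmentation leaves 5 relabeled analysis bins", {
  slab <- make_phantom_ribbon("slab", 0, 2.1, voxel_size = 0.1,
                              grid_shape = c(8, 8, 23))
  bins7 <- assign_depth_bins(slab, 7)
  bins5 <- trim_extreme_bins(bins7, 7)
  expect_equal(sort(unique(bins5[bins5 > 0])), 1:5)
  expect_equal(sum(bins5 > 0), sum(bins7 %in% 2:6))
  # relabeling preserves depth order: old bin 2 -> new bin 1
  expect_true(all(bins5[bins7 == 2L] == 1L))
})

test_that("depth bins from a geometric coordinate use the equivolume transform", {
  rho <- array(rep(seq(0.05, 0.95, length.out = 10), each = 4), c(4, 10, 1))
  bins <- depth_bins_from_rho(rho, A_w = 1, A_p = 2, K = 2)
  # equal-volume boundary at rho = sqrt(2.5) - 1 ~ 0.581, not 0.5
  expect_equal(unique(bins[rho < 0.58]), 1L)
  expect_equal(unique(bins[rho > 0.582]), 2L)
})

test_that("depth profiles aggregate cells and report empty ones", {
  slab <- make_phantom_ribbon("slab", 0, 2, voxel_size = 0.2,
                              grid_shape = c(10, 10, 12))
  bins <- assign_depth_bins(slab, 5)
  parcels <- array(0L, dim(slab$labels))
  parcels[1:5, , ] <- 1L
  parcels[6:10, , ] <- 2L
  # ratio equal to bin index reproduces the labels
  vals <- array(NA_real_, dim(bins)); vals[bins > 0] <- bins[bins > 0]
  rv <- ratio_volume(vals, bins > 0)
  prof <- extract_depth_profiles(rv, bins, parcels, K = 5)
  expect_equal(nrow(prof), 10L)
  expect_equal(prof$mean_ratio, prof$depth_bin)
  expect_true(all(prof$n_voxels == 100L))  # 1000 ribbon voxels / 2 parcels / 5 bins

  # constant volume -> constant means
  vals2 <- array(NA_real_, dim(bins)); vals2[bins > 0] <- 1.4
  prof2 <- extract_depth_profiles(ratio_volume(vals2, bins > 0), bins, parcels, K = 5)
  expect_true(all(prof2$mean_ratio == 1.4))

  # a parcel with no voxels in one bin yields an explicit empty row
  bins_gap <- bins
  bins_gap[parcels == 2L & bins == 3L] <- 0L
  expect_warning(
    prof3 <- extract_depth_profiles(rv, bins_gap, parcels, K = 5),
    "empty"
  )
  empty <- prof3[prof3$parcel == 2 & prof3$depth_bin == 3, ]
  expect_equal(empty$n_voxels, 0L)
  expect_true(is.na(empty$mean_ratio))
})

test_that("synthetic deep-to-superficial gradient yields decreasing profiles", {
  ann <- make_phantom_ribbon("annulus", 10, 12, voxel_size = 0.1,
                             grid_shape = c(280, 280, 2))
  al <- ribbon_alpha(ann)
  bins <- assign_depth_bins(ann, 6)
  vals <- array(NA_real_, dim(al))
  vals[!is.na(al)] <- 2 - al[!is.na(al)]  # deep (alpha=0) highest
  parcels <- array(1L, dim(al))
  prof <- extract_depth_profiles(ratio_volume(vals, !is.na(al)), bins, parcels, K = 6)
  expect_true(all(diff(prof$mean_ratio) < 0))
})
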