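test_that("volume fraction is the ROI-normalized voxel count", {
  d <- c(10, 12, 12)
  roi <- volume_grid(array(TRUE, d), 1, "binary")
  expect_equal(volume_fraction(roi, roi), 100)
  half <- array(FALSE, d); half[1:5, , ] <- TRUE
  expect_equal(volume_fraction(volume_grid(half, 1, "binary"), roi), 50)
})

test_that("local thickness matches the inscribed-sphere oracle", {
  ball <- make_ball_mask(15)
  th <- local_thickness(ball)
  expect_lte(abs(max(th$values) - 15), 1)
  oracle <- brute_thickness(ball)
  expect_equal(th$values, oracle, tolerance = 1e-12)
  # an isolated voxel measures two voxel widths (2 * dt convention)
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_equal(local_thickness(volume_grid(m, 1, "binary"))$values[3, 3, 3], 2)
})

test_that("a 20-voxel cylinder measures 20 +/- 1 voxels on its axis", {
  tube <- make_tube_mask(d = c(30, 26, 26), diameter_vox = 20,
                         center = c(14, 14))
  th <- local_thickness(tube)
  axis_mean <- mean(th$values[, 14, 14][th$values[, 14, 14] > 0])
  expect_equal(axis_mean, 20, tolerance = 1 / 20)
  # and agrees with the brute-force oracle on the axis
  oracle <- brute_thickness(tube)
  expect_lte(max(abs(th$values[, 14, 14] - oracle[, 14, 14])), 1)
})

test_that("slab thickness equals its analytic height", {
  d <- c(20, 15, 15)
  for (t_vox in c(5, 9)) {
    m <- array(FALSE, d); m[1:t_vox + 5, , ] <- TRUE
    bth <- mean_structure_thickness(volume_grid(m, 1, "binary"))
    expect_lte(abs(bth - t_vox), 1 + 1e-9)
  }
  # ball: mean below the maximum, maximum equals the diameter
  ball <- make_ball_mask(15)
  th <- local_thickness(ball)
  expect_lt(mean_structure_thickness(ball, th), max(th$values))
  expect_lte(abs(max(th$values) - 15), 1)
  # empty mask reports missing, not zero
  empty <- volume_grid(array(FALSE, c(4, 4, 4)), 1, "binary")
  expect_true(is.na(mean_structure_thickness(empty)))
})

test_that("skeletons of tubes have the expected graph structure", {
  tube <- make_tube_mask()
  sk <- skeletonize(tube)
  expect_equal(sk$n_segments, 1)
  expect_equal(sk$n_nodes, 0)
  expect_equal(sk$n_free_ends, 2)

  d2 <- c(48, 40, 25)
  segs <- rbind(c(2, 20, 12, 24, 20, 12, 3.5),
                c(24, 20, 12, 45, 10, 12, 3),
                c(24, 20, 12, 45, 30, 12, 3))
  y <- volume_grid(array(kesct:::rasterize_tubes_cpp(as.integer(d2), segs), d2),
                   1, "binary")
  sky <- skeletonize(y)
  expect_equal(sky$n_segments, 3)
  expect_equal(sky$n_nodes, 1)
  expect_equal(sky$n_free_ends, 3)
})

test_that("segment counts equal the generating tree's edge count", {
  segs <- make_tree_segments()
  ph <- build_phantom(tree_phantom_spec())
  sk <- skeletonize(ph$truth$vessel_mask)
  expect_equal(sk$n_segments, nrow(segs))
  expect_equal(sk$n_nodes, 3)
  expect_equal(sk$n_free_ends, 5)
})

test_that("segment density is count per ROI volume", {
  tube <- make_tube_mask()
  sk <- skeletonize(tube)
  expect_equal(segment_density(sk, 0.122) * 0.122, 1)
  # 122 segments in 0.122 mm^3 give 1000 per mm^3
  sk122 <- sk; sk122$n_segments <- 122L
  expect_equal(segment_density(sk122, 0.122), 1000)
  sk0 <- sk; sk0$n_segments <- 0L
  expect_equal(segment_density(sk0, 0.122), 0)
  expect_error(segment_density(sk, 0), "positive")
})

test_that("mean skeleton diameter averages local diameters over the skeleton", {
  # one cylinder, diameter 20 um at 1 um voxels
  tube <- make_tube_mask(d = c(30, 26, 26), diameter_vox = 20, center = c(14, 14))
  th <- local_thickness(tube)
  sk <- skeletonize(tube)
  expect_equal(mean_skeleton_diameter(sk, th), 20, tolerance = 1.2 / 20)
  # two equal-length cylinders of 10 and 30: mean about 20 (thinning erodes
  # thick-tube ends by about one radius, hence long tubes and a modest band)
  d <- c(120, 64, 42)
  segs <- rbind(c(1, 16, 20, 118, 16, 20, 5),
                c(1, 45, 20, 118, 45, 20, 15))
  m <- volume_grid(array(kesct:::rasterize_tubes_cpp(as.integer(d), segs), d),
                   1, "binary")
  th2 <- local_thickness(m)
  sk2 <- skeletonize(m)
  expect_lte(abs(mean_skeleton_diameter(sk2, th2) - 20), 1.5)
  # empty skeleton: missing value, not zero
  empty <- volume_grid(array(FALSE, c(4, 4, 4)), 1, "binary")
  expect_true(is.na(mean_skeleton_diameter(skeletonize(empty),
                                           local_thickness(empty))))
})

test_that("size-specific quantities partition the totals exactly", {
  ph <- build_phantom(small_phantom_spec())
  roi <- roi_mask(phantom_roi(small_phantom_spec()), ph$pair$low)
  res <- run_specimen(ph$pair, roi = phantom_roi(small_phantom_spec()),
                      register = FALSE)
  m <- res$morphometry
  expect_equal(sum(m$per_bin$vvf_pct), m$vvf_pct, tolerance = 1e-12)
  expect_equal(sum(m$per_bin$seg_per_mm3), m$vseg_per_mm3, tolerance = 1e-12)
  expect_true(all(m$per_bin$vvf_pct >= 0))
  expect_lte(m$vvf_pct, 100)
  expect_lte(m$bvf_pct, 100)
})

test_that("two parallel tubes split volume across bins as their tube volumes", {
  # diameters 10 um and 40 um, equal length: volumes 1:16
  d <- c(40, 60, 30)
  segs <- rbind(c(2, 15, 15, 37, 15, 15, 5),
                c(2, 42, 15, 37, 42, 15, 20))
  m <- volume_grid(array(kesct:::rasterize_tubes_cpp(as.integer(d), segs), d),
                   1, "binary")
  roi <- volume_grid(array(TRUE, d), 1, "binary")
  th <- local_thickness(m)
  sk <- skeletonize(m)
  ss <- size_specific(sk, m, roi, th)
  v10 <- ss$vvf_pct[ss$bin == "10-20"]
  v40 <- ss$vvf_pct[ss$bin == ">40"]
  expect_equal(ss$n_segments[ss$bin == "10-20"], 1L)
  expect_equal(ss$n_segments[ss$bin == ">40"], 1L)
  expect_equal(v40 / v10, 16, tolerance = 0.2)
})

test_that("micrometer outputs scale with the voxel size", {
  tube1 <- make_tube_mask(voxel_um = 1)
  tube2 <- make_tube_mask(voxel_um = 2)
  th1 <- mean_skeleton_diameter(skeletonize(tube1), local_thickness(tube1))
  th2 <- mean_skeleton_diameter(skeletonize(tube2), local_thickness(tube2))
  expect_equal(th2, 2 * th1)
})

test_that("indices are stable under 90-degree rotations of the structure", {
  ph <- build_phantom(tree_phantom_spec())
  m <- ph$truth$vessel_mask
  roi <- volume_grid(array(TRUE, dim(m$values)), m$voxel_um, "binary")
  base_sk <- skeletonize(m)
  base_vvf <- volume_fraction(m, roi)
  rot <- volume_grid(aperm(m$values, c(2, 1, 3))[, dim(m$values)[1]:1, ],
                     m$voxel_um, "binary")
  roi_r <- volume_grid(array(TRUE, dim(rot$values)), m$voxel_um, "binary")
  expect_equal(volume_fraction(rot, roi_r), base_vvf)
  rot_sk <- skeletonize(rot)
  expect_lte(abs(rot_sk$n_segments - base_sk$n_segments),
             ceiling(0.05 * base_sk$n_segments))
})
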