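test_that("a vessel-free spec yields an empty truth mask", {
  empty_segs <- data.frame(p1x = numeric(0), p1y = numeric(0), p1z = numeric(0),
                           p2x = numeric(0), p2y = numeric(0), p2z = numeric(0),
                           radius_um = numeric(0), tree = integer(0),
                           edge = integer(0))
  ph <- build_phantom(small_phantom_spec(vessel_segments = empty_segs))
  expect_equal(sum(ph$truth$vessel_mask$values), 0)
  ti <- truth_indices(ph$truth)
  expect_equal(ti$vvf_pct, 0)
  expect_equal(ti$vseg_per_mm3, 0)
})

test_that("a single axial tube produces the expected analytic truth", {
  d_um <- 20
  spec <- phantom_spec(roi_diameter_um = 150, roi_height_um = 120,
                       vessel_segments = data.frame(
                         p1x = 0, p1y = 103, p1z = 103, p2x = 400,
                         p2y = 103, p2z = 103, radius_um = d_um / 2,
                         tree = 1L, edge = 1L),
                       bone_regions = list(), blur_sigma_um = 0,
                       noise_sd_gray = 0, misalignment = rigid_transform(),
                       seed = 1)
  ph <- build_phantom(spec)
  ti <- truth_indices(ph$truth)
  expect_equal(ti$vd_um, 20)
  expect_equal(ti$vseg_per_mm3 * ti$roi_volume_mm3, 1)
  expect_equal(ti$bvf_pct, 0)
  in_bin <- ti$per_bin$bin[ti$per_bin$vvf_pct > 0]
  expect_identical(in_bin, "20-30")
  expect_equal(sum(ti$per_bin$vvf_pct), ti$vvf_pct)
  # truth V.Vf equals the mask voxel count over the ROI count
  rm_ <- roi_mask(phantom_roi(spec), ph$pair$low)
  expect_equal(ti$vvf_pct,
               100 * sum(ph$truth$vessel_mask$values & rm_$values) /
                 sum(rm_$values))
})

test_that("rasterized tube volume tracks the analytic volume", {
  for (dia_vox in c(4, 6, 10)) {
    d <- c(40, 8 + 3 * dia_vox, 8 + 3 * dia_vox)
    tube <- make_tube_mask(d = d, diameter_vox = dia_vox)
    len <- d[1] - 3 # clipped centerline length in voxels
    # capped tube (capsule): cylinder plus two hemispherical end caps
    analytic <- pi * (dia_vox / 2)^2 * len + 4 / 3 * pi * (dia_vox / 2)^3
    expect_gt(sum(tube$values) / analytic, 0.9)
    expect_lt(sum(tube$values) / analytic, 1.1)
  }
})

test_that("the generated energies embody the K-edge physics", {
  spec <- small_phantom_spec(blur_sigma_um = 0, noise_sd_gray = 0,
                             misalignment = rigid_transform())
  ph <- build_phantom(spec)
  v <- ph$truth$vessel_mask$values
  b <- ph$truth$bone_mask$values
  expect_false(any(v & b))
  # vessels jump across the edge; bone does not (identical within 1%)
  expect_true(mean(ph$pair$high$values[v]) >
                mean(ph$pair$low$values[v]) + 50)
  expect_lt(abs(mean(ph$pair$high$values[b]) / mean(ph$pair$low$values[b]) - 1),
            0.01)
})

test_that("the same seed reproduces both volumes bit-exactly", {
  s1 <- build_phantom(small_phantom_spec(seed = 42))
  s2 <- build_phantom(small_phantom_spec(seed = 42))
  expect_identical(s1$pair$low$values, s2$pair$low$values)
  expect_identical(s1$pair$high$values, s2$pair$high$values)
  s3 <- build_phantom(small_phantom_spec(seed = 43))
  expect_false(identical(s1$pair$low$values, s3$pair$low$values))
})

test_that("the misalignment is applied to the sub-edge volume only", {
  aligned <- build_phantom(small_phantom_spec(
    noise_sd_gray = 0, misalignment = rigid_transform()))
  shifted <- build_phantom(small_phantom_spec(
    noise_sd_gray = 0, misalignment = rigid_transform(c(3, 0, 0))))
  expect_identical(aligned$pair$high$values, shifted$pair$high$values)
  expect_false(identical(aligned$pair$low$values, shifted$pair$low$values))
  # an integer shift moves the sub-edge content exactly
  d <- dim(aligned$pair$low$values)
  expect_equal(shifted$pair$low$values[4:d[1], , ],
               aligned$pair$low$values[1:(d[1] - 3), , ])
})

test_that("contradictory overlapping primitives are rejected", {
  segs <- data.frame(p1x = 100, p1y = 110, p1z = 110, p2x = 300,
                     p2y = 110, p2z = 110, radius_um = 10, tree = 1L,
                     edge = 1L)
  spec <- phantom_spec(roi_diameter_um = 220, roi_height_um = 150,
                       vessel_segments = segs,
                       bone_regions = list(
                         bone_region("sphere", dhap = 800,
                                     center = c(200, 110, 110), radius = 30)),
                       blur_sigma_um = 0, noise_sd_gray = 0,
                       misalignment = rigid_transform(), seed = 1)
  expect_error(build_phantom(spec), "overlap")
  # overlapping bone primitives with different densities also clash
  spec2 <- phantom_spec(roi_diameter_um = 220, roi_height_um = 150,
                        vessel_segments = segs[0, ],
                        bone_regions = list(
                          bone_region("sphere", dhap = 800,
                                      center = c(200, 110, 110), radius = 30),
                          bone_region("sphere", dhap = 900,
                                      center = c(210, 110, 110), radius = 30)),
                        seed = 1)
  expect_error(build_phantom(spec2), "contradictory")
})

test_that("sub-voxel radii warn and still rasterize a connected line", {
  segs <- data.frame(p1x = 100, p1y = 110, p1z = 110, p2x = 300,
                     p2y = 110, p2z = 110, radius_um = 1, tree = 1L,
                     edge = 1L)
  spec <- phantom_spec(roi_diameter_um = 220, roi_height_um = 150,
                       vessel_segments = segs, bone_regions = list(),
                       blur_sigma_um = 0, noise_sd_gray = 0,
                       misalignment = rigid_transform(), seed = 1)
  expect_warning(ph <- build_phantom(spec), "one voxel")
  expect_gt(sum(ph$truth$vessel_mask$values), 30)
  sk <- skeletonize(ph$truth$vessel_mask)
  expect_equal(sk$n_segments, 1)
})

test_that("truth indices reproduce simple arithmetic", {
  ph <- build_phantom(tree_phantom_spec())
  ti <- truth_indices(ph$truth)
  expect_equal(ti$vseg_per_mm3 * ti$roi_volume_mm3, 7)
  expect_equal(sum(ti$per_bin$seg_per_mm3), ti$vseg_per_mm3)
})
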