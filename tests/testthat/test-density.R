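test_that("uniform-density bone lands in a single bin", {
  cal <- calibration_line(gray_to_mu_factor = 7.97 / 136)
  gray742 <- mu_to_gray(dhap_to_mu(742, cal), cal) # integer-valued by design
  low <- volume_grid(array(round(gray742), c(8, 8, 8)))
  mask <- volume_grid(array(TRUE, c(8, 8, 8)), semantics = "binary")
  h <- dhap_distribution(mask, low, cal, mean_filter_size = 1L)
  dh <- mu_to_dhap(gray_to_mu(round(gray742), cal), cal)
  hit <- h$bins[h$bins$percent > 0, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$bin_left, dh)
  expect_gt(hit$bin_right, dh)
  expect_equal(hit$percent, 100)
  expect_equal(h$mean_dhap, dh)
  expect_equal(h$median_dhap, dh)
})

test_that("a uniform density spread gives a flat histogram with mean 700", {
  set.seed(8)
  cal <- calibration_line()
  n <- 40
  dh_true <- runif(n^3, 500, 900)
  gray <- mu_to_gray(dhap_to_mu(dh_true, cal), cal)
  low <- volume_grid(array(gray, c(n, n, n)))
  mask <- volume_grid(array(TRUE, c(n, n, n)), semantics = "binary")
  h <- dhap_distribution(mask, low, cal, mean_filter_size = 1L)
  expect_equal(h$mean_dhap, 700, tolerance = 0.005)
  inner <- h$bins$percent[h$bins$bin_left >= 508 & h$bins$bin_right <= 892]
  expect_lt(stats::sd(inner) / mean(inner), 0.25)
  expect_equal(sum(h$bins$percent), 100, tolerance = 1e-6)
})

test_that("histogram mean and median agree with the raw-voxel summaries", {
  set.seed(3)
  cal <- calibration_line()
  n <- 24
  dh_true <- 500 + rexp(n^3, 1 / 150)
  gray <- mu_to_gray(dhap_to_mu(dh_true, cal), cal)
  low <- volume_grid(array(pmin(gray, 255), c(n, n, n)))
  mask <- volume_grid(array(TRUE, c(n, n, n)), semantics = "binary")
  h <- dhap_distribution(mask, low, cal, mean_filter_size = 1L)
  mids <- (h$bins$bin_left + h$bins$bin_right) / 2
  mean_from_hist <- sum(mids * h$bins$percent) / 100
  expect_lte(abs(mean_from_hist - h$mean_dhap), h$bin_width / 2)
  cum <- cumsum(h$bins$percent)
  med_bin <- which(cum >= 50)[1]
  expect_gte(h$median_dhap, h$bins$bin_left[med_bin] - h$bin_width / 2)
  expect_lte(h$median_dhap, h$bins$bin_right[med_bin] + h$bin_width / 2)
})

test_that("a uniform phantom bone region recovers its generative density", {
  # a bone slab spanning the ROI, no blur: the only perturbations are the
  # additive gray noise and 8-bit quantization, so the recovered mean obeys
  # a CLT-style bound around the generative 830 mg/cm^3
  d_um <- 220
  spec <- phantom_spec(roi_diameter_um = d_um, roi_height_um = 150,
                       vessel_segments = data.frame(
                         p1x = numeric(0), p1y = numeric(0), p1z = numeric(0),
                         p2x = numeric(0), p2y = numeric(0), p2z = numeric(0),
                         radius_um = numeric(0), tree = integer(0),
                         edge = integer(0)),
                       bone_regions = list(
                         bone_region("slab", dhap = 830, lo = c(0, 0, 0),
                                     hi = rep(1000, 3))),
                       blur_sigma_um = 0, misalignment = rigid_transform(),
                       seed = 5)
  ph <- build_phantom(spec)
  res <- run_specimen(ph$pair, roi = phantom_roi(spec), register = FALSE)
  # noise: 2 gray ~ 107 mg/cm^3 per voxel before averaging; with n bone
  # voxels the mean is tight, leaving quantization as the dominant residual
  n <- res$density$n_voxels
  sigma_dhap <- 2 * spec$cal$gray_to_mu_factor * spec$cal$slope_mu_to_dhap
  bound <- max(2 * sigma_dhap / sqrt(n), 10)
  expect_lt(abs(res$density$mean_dhap - 830), bound)
})

test_that("recovered bone density responds monotonically to the phantom", {
  means <- vapply(c(700, 830, 950), function(dh) {
    spec <- small_phantom_spec(dhap_regenerated = dh, seed = 5)
    ph <- build_phantom(spec)
    res <- run_specimen(ph$pair, roi = phantom_roi(spec), register = TRUE,
                        registration_args = list(rotations = FALSE,
                                                 max_shift_vox = 4))
    res$density$mean_dhap
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("empty bone mask reports a missing summary", {
  low <- volume_grid(array(0, c(6, 6, 6)))
  none <- volume_grid(array(FALSE, c(6, 6, 6)), semantics = "binary")
  h <- dhap_distribution(none, low)
  expect_equal(h$n_voxels, 0L)
  expect_true(is.na(h$mean_dhap))
})

test_that("group histogram averaging preserves normalization", {
  set.seed(12)
  cal <- calibration_line()
  hs <- lapply(1:3, function(i) {
    dh <- 500 + rexp(20^3, 1 / (100 + 40 * i))
    gray <- pmin(mu_to_gray(dhap_to_mu(dh, cal), cal), 255)
    dhap_distribution(volume_grid(array(TRUE, c(20, 20, 20)),
                                  semantics = "binary"),
                      volume_grid(array(gray, c(20, 20, 20))), cal,
                      mean_filter_size = 1L)
  })
  avg <- average_dhap_histograms(hs)
  expect_equal(sum(avg$percent), 100, tolerance = 1e-6)
  pooled <- average_dhap_histograms(hs, pooled = TRUE)
  expect_equal(sum(pooled$percent), 100, tolerance = 1e-6)
})
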