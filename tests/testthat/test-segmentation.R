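test_that("3D maximum filter matches the exhaustive neighborhood oracle", {
  set.seed(1)
  n <- 16
  v <- array(runif(n^3, 0, 255), c(n, n, n))
  got <- max_filter3d(v, 1)
  expect_true(all(got >= v))
  oracle <- array(0, dim(v))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    oracle[i, j, k] <- max(v[max(1, i - 1):min(n, i + 1),
                             max(1, j - 1):min(n, j + 1),
                             max(1, k - 1):min(n, k + 1)])
  expect_equal(got, oracle)
  # single bright voxel expands to a 3x3x3 block
  z <- array(0, c(9, 9, 9)); z[5, 5, 5] <- 7
  mz <- max_filter3d(z, 1)
  expect_equal(sum(mz == 7), 27)
  # constants are fixed points
  cst <- array(3, c(6, 6, 6))
  expect_equal(max_filter3d(cst, 1), cst)
})

test_that("3D mean filter matches the exhaustive box-average oracle", {
  set.seed(2)
  n <- 16
  v <- array(runif(n^3, 0, 255), c(n, n, n))
  got <- mean_filter3d(v, 3)
  oracle <- array(0, dim(v))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    oracle[i, j, k] <- mean(v[max(1, i - 1):min(n, i + 1),
                              max(1, j - 1):min(n, j + 1),
                              max(1, k - 1):min(n, k + 1)])
  expect_equal(got, oracle)
  cst <- array(3, c(6, 6, 6))
  expect_equal(mean_filter3d(cst, 3), cst)
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  mi <- mean_filter3d(imp, 3)
  expect_equal(mi[4:6, 4:6, 4:6], array(1 / 27, c(3, 3, 3)))
})

test_that("K-edge subtraction clamps and preserves the contrast jump", {
  a <- volume_grid(array(120, c(4, 4, 4)))
  b <- volume_grid(array(40, c(4, 4, 4)))
  expect_equal(subtract_kedge(a, b)$values[1], 80)
  expect_equal(subtract_kedge(b, a)$values[1], 0)
  expect_equal(subtract_kedge(b, a, clamp = FALSE)$values[1], -80)
  expect_error(subtract_kedge(a, volume_grid(array(0, c(5, 4, 4)))),
               "lattice")

  # on a clean phantom the mean difference over truth vessel voxels equals
  # the K-edge attenuation jump divided by the gray scaling
  spec <- phantom_spec(roi_diameter_um = 200, roi_height_um = 120,
                       blur_sigma_um = 0, noise_sd_gray = 0,
                       misalignment = rigid_transform(), seed = 2)
  ph <- build_phantom(spec)
  dm <- ph$pair$high$values - ph$pair$low$values
  expected <- (spec$mu_vessel_high - spec$mu_vessel_low) /
    spec$cal$gray_to_mu_factor
  expect_equal(mean(dm[ph$truth$vessel_mask$values]), expected,
               tolerance = 0.01)
})

test_that("Li threshold is the exhaustive cross-entropy minimizer", {
  set.seed(1)
  x <- c(rnorm(5e4, 20, 8), rnorm(5e4, 150, 8))
  x <- pmin(pmax(round(x), 1), 255)
  thr <- li_threshold(x)
  # independent exhaustive scan of the criterion over all split points
  eta <- brute_li_criterion(x)
  u <- sort(unique(x))
  split <- which.min(eta)
  expect_gt(thr, u[split])
  expect_lte(thr, u[split + 1])
  # the classical iterative fixed-point form induces the same partition
  t_it <- mean(x)
  for (i in 1:100) {
    m0 <- mean(x[x < t_it]); m1 <- mean(x[x >= t_it])
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (abs(t_new - t_it) < 1e-8) break
    t_it <- t_new
  }
  expect_identical(x >= thr, x >= t_it)
})

test_that("Li threshold separates two-level data and shifts with offsets", {
  two <- c(rep(10, 500), rep(200, 500))
  thr <- li_threshold(two)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  set.seed(1)
  x <- c(rnorm(5e4, 20, 8), rnorm(5e4, 150, 8))
  x <- pmin(pmax(round(x), 1), 255)
  base <- li_threshold(x)
  for (cc in c(5, 10, 25))
    expect_lte(abs(li_threshold(x + cc) - base - cc), 1)
  expect_error(li_threshold(rep(7, 100)), "degenerate")
})

test_that("vessel and bone masks are recovered on a clean phantom", {
  spec <- small_phantom_spec(blur_sigma_um = 0, noise_sd_gray = 0,
                             misalignment = rigid_transform())
  ph <- build_phantom(spec)
  roi <- roi_mask(phantom_roi(spec), ph$pair$low)
  vessels <- segment_vessels(ph$pair, roi = roi)
  bone <- segment_bone(ph$pair$low, vessels, spec$cal, roi = roi)
  expect_false(any(vessels$values & bone$values)) # disjoint by construction
  vt <- ph$truth$vessel_mask$values & roi$values
  bt <- ph$truth$bone_mask$values & roi$values
  expect_gte(dice_coef(vessels$values, vt), 0.9)
  expect_gte(dice_coef(bone$values, bt), 0.9)
})

test_that("a vessel-free phantom yields an (almost) empty vascular mask", {
  spec <- small_phantom_spec(vessel_segments = data.frame(
    p1x = numeric(0), p1y = numeric(0), p1z = numeric(0),
    p2x = numeric(0), p2y = numeric(0), p2z = numeric(0),
    radius_um = numeric(0), tree = integer(0), edge = integer(0)),
    misalignment = rigid_transform())
  ph <- build_phantom(spec)
  roi <- roi_mask(phantom_roi(spec), ph$pair$low)
  vessels <- segment_vessels(ph$pair, roi = roi)
  expect_lt(100 * sum(vessels$values) / sum(roi$values), 0.1)
})

test_that("skipping registration of a shifted pair degrades segmentation", {
  # shift perpendicular to the predominantly axial vessels; the sub-edge
  # volume carries the bone information, so misregistration displaces the
  # bone compartment and leaves partial-volume residuals in the subtraction
  spec <- small_phantom_spec(misalignment = rigid_transform(c(0, 3, 0)))
  ph <- build_phantom(spec)
  roi <- roi_mask(phantom_roi(spec), ph$pair$low)
  vt <- ph$truth$vessel_mask$values & roi$values
  bt <- ph$truth$bone_mask$values & roi$values
  seg_dice <- function(pair) {
    v <- segment_vessels(pair, roi = roi)
    b <- segment_bone(pair$low, v, roi = roi)
    c(vessel = dice_coef(v$values, vt), bone = dice_coef(b$values, bt))
  }
  raw <- seg_dice(ph$pair)
  reg <- seg_dice(align_pair(ph$pair, rotations = FALSE))
  expect_gt(reg[["bone"]], raw[["bone"]])
  expect_gt(mean(reg), mean(raw))
  # the unregistered bone mask is visibly displaced
  expect_lt(raw[["bone"]], 0.8)
  expect_gt(reg[["bone"]], 0.85)
})

test_that("stronger K-edge contrast never shrinks the recovered vessels", {
  base <- small_phantom_spec(blur_sigma_um = 0, noise_sd_gray = 0,
                             misalignment = rigid_transform())
  vols <- vapply(c(30, 60, 120), function(mu_hi) {
    spec <- small_phantom_spec(blur_sigma_um = 0, noise_sd_gray = 0,
                               misalignment = rigid_transform(),
                               mu_vessel_high = mu_hi)
    ph <- build_phantom(spec)
    roi <- roi_mask(phantom_roi(spec), ph$pair$low)
    sum(segment_vessels(ph$pair, roi = roi)$values)
  }, 0)
  expect_true(all(diff(vols) >= 0))
})

test_that("bone rule keeps mineralized voxels and excludes vessels", {
  cal <- calibration_line()
  block <- volume_grid(array(round(mu_to_gray(dhap_to_mu(800, cal), cal)),
                             c(10, 10, 10)))
  none <- volume_grid(array(FALSE, c(10, 10, 10)), semantics = "binary")
  all_v <- volume_grid(array(TRUE, c(10, 10, 10)), semantics = "binary")
  expect_true(all(segment_bone(block, none, cal)$values))
  expect_false(any(segment_bone(block, all_v, cal)$values))
})
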