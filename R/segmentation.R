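#' Segmentation parameters
#'
#' @param max_filter_radius Radius of the 3D maximum filter used to expand
#'   bone in the sub-edge volume before subtraction; 1 gives the 3x3x3
#'   neighborhood.
#' @param mean_filter_size Edge length of the cubic averaging filter (odd),
#'   default 3.
#' @param bone_mu_threshold Attenuation threshold (/cm) above which
#'   extravascular voxels are classified as bone.
#' @param clamp Clamp the subtraction image at 0 (default `TRUE`).
#' @param exclude_zero Exclude exactly-zero voxels from the threshold
#'   histogram (default `TRUE`); after clamping, zeros carry no vascular
#'   signal and would otherwise dominate the background class.
#' @param min_threshold_gray Floor on the vascular threshold, in gray
#'   levels (default 8). When no contrast agent is present the difference
#'   image is pure noise and a histogram split would label its bright tail
#'   as vessels; any genuine K-edge jump is far above this floor (the
#'   default contrast corresponds to over 100 gray levels).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(max_filter_radius = 1L, mean_filter_size = 3L,
                                bone_mu_threshold = 4.74, clamp = TRUE,
                                exclude_zero = TRUE, min_threshold_gray = 8) {
  if (mean_filter_size %% 2 != 1 || mean_filter_size < 1)
    stop("`mean_filter_size` must be odd and >= 1")
  if (max_filter_radius < 1) stop("`max_filter_radius` must be >= 1")
  structure(list(max_filter_radius = as.integer(max_filter_radius),
                 mean_filter_size = as.integer(mean_filter_size),
                 bone_mu_threshold = bone_mu_threshold,
                 clamp = clamp, exclude_zero = exclude_zero,
                 min_threshold_gray = min_threshold_gray),
            class = "segmentation_params")
}

#' 3D maximum filter
#'
#' Replaces each voxel by the maximum over its cubic neighborhood of radius
#' `radius` (a (2r+1)^3 box, clipped at the lattice edge). Used to expand
#' bone in the sub-edge volume so that partial-volume residuals at bone
#' boundaries cancel in the subtraction image.
#'
#' @param vol A [volume_grid] (or plain 3D array).
#' @param radius Neighborhood radius in voxels (>= 1).
#' @return Filtered volume, same class as the input.
#' @export
max_filter3d <- function(vol, radius = 1L) {
  if (radius < 1) stop("`radius` must be >= 1")
  if (inherits(vol, "volume_grid")) {
    out <- vol
    out$values <- max_filter3d(vol$values, radius)
    return(out)
  }
  array(max_filter3d_cpp(as.numeric(vol), as.integer(dim(vol)), as.integer(radius)),
        dim(vol))
}

#' 3D box (mean) filter
#'
#' Cubic moving average of edge length `size` (odd); at the lattice edge the
#' window is clipped and the mean is taken over the in-bounds voxels, so
#' constants are preserved everywhere.
#'
#' @param vol A [volume_grid] (or plain 3D array).
#' @param size Box edge length in voxels (odd), default 3.
#' @return Filtered volume, same class as the input.
#' @export
mean_filter3d <- function(vol, size = 3L) {
  if (size %% 2 != 1 || size < 1) stop("`size` must be odd and >= 1")
  if (inherits(vol, "volume_grid")) {
    out <- vol
    out$values <- mean_filter3d(vol$values, size)
    return(out)
  }
  array(mean_filter3d_cpp(as.numeric(vol), as.integer(dim(vol)),
                          as.integer((size - 1) / 2)),
        dim(vol))
}

#' K-edge subtraction image
#'
#' Voxel-wise difference supra-edge minus (bone-expanded) sub-edge volume,
#' clamped at 0 by default: negative differences carry no vascular signal.
#'
#' @param high Supra-edge (18.1 keV) [volume_grid].
#' @param low_expanded Sub-edge volume after maximum-filter expansion, on
#'   the same lattice.
#' @param clamp Clamp negatives at 0 (default `TRUE`).
#' @return A [volume_grid] of gray-level differences.
#' @export
subtract_kedge <- function(high, low_expanded, clamp = TRUE) {
  stopifnot_same_lattice(high, low_expanded)
  out <- high
  v <- high$values - low_expanded$values
  if (clamp) v[v < 0] <- 0
  out$values <- v
  out
}

#' Minimum cross-entropy (Li) threshold
#'
#' Exhaustive minimization of the Li-Lee cross-entropy criterion
#' `-(A0 log m0 + A1 log m1)` over all candidate split points of the
#' intensity histogram, where `A` and `m` are the intensity sum and mean of
#' the below/above classes. The returned threshold is the midpoint between
#' the adjacent intensity levels at the optimal split; foreground is
#' `values >= threshold`. The exhaustive scan is deterministic and agrees
#' with the classical iterative fixed-point form (a property exercised in
#' the tests).
#'
#' @param vol A [volume_grid] or numeric vector/array of non-negative
#'   intensities.
#' @param exclude_zero Drop exactly-zero values from the histogram before
#'   thresholding (default `TRUE`).
#' @param mask Optional logical array restricting the histogram (e.g. an
#'   ROI).
#' @return Threshold (scalar), with attribute `class_means = c(below, above)`.
#' @export
li_threshold <- function(vol, exclude_zero = TRUE, mask = NULL) {
  v <- if (inherits(vol, "volume_grid")) vol$values else vol
  v <- as.numeric(v)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "volume_grid")) mask$values else mask
    v <- v[as.logical(m)]
  }
  if (exclude_zero) v <- v[v != 0]
  if (length(v) == 0 || any(v < 0))
    stop("li_threshold needs non-negative, non-empty intensities")
  vs <- sort(v)
  r <- rle(vs)
  u <- r$values
  cnt <- as.numeric(r$lengths)
  if (length(u) < 2L) stop("degenerate histogram: fewer than 2 distinct values")
  csum_n <- cumsum(cnt)
  csum_a <- cumsum(cnt * u)
  K <- length(u)
  # split i: below = u[1..i], above = u[(i+1)..K]
  n0 <- csum_n[-K]; a0 <- csum_a[-K]
  n1 <- csum_n[K] - n0; a1 <- csum_a[K] - a0
  m0 <- a0 / n0; m1 <- a1 / n1
  # guard log of a zero mean (possible when the lowest level is 0)
  eta <- -(a0 * log(pmax(m0, .Machine$double.xmin)) + a1 * log(m1))
  i <- which.min(eta)
  thr <- (u[i] + u[i + 1]) / 2
  attr(thr, "class_means") <- c(below = m0[i], above = m1[i])
  thr
}

#' Segment the vascular compartment of a registered dual-energy pair
#'
#' Pipeline: maximum-filter expansion of the sub-edge volume, K-edge
#' subtraction (clamped at 0), 3x3x3 averaging, then minimum cross-entropy
#' thresholding of the difference image (global over the ROI when one is
#' given).
#'
#' @param pair A registered [dual_energy_pair] (apply [align_pair()] first
#'   if the energies are misaligned).
#' @param params A [segmentation_params].
#' @param roi Optional binary [volume_grid] restricting the threshold
#'   histogram and the output mask.
#' @return Binary [volume_grid] of vascular voxels, with attributes
#'   `threshold` (gray levels) and `difference` (the filtered subtraction
#'   image).
#' @export
segment_vessels <- function(pair, params = segmentation_params(), roi = NULL) {
  stopifnot(inherits(pair, "dual_energy_pair"))
  low_exp <- max_filter3d(pair$low, params$max_filter_radius)
  diff <- subtract_kedge(pair$high, low_exp, clamp = params$clamp)
  diff <- mean_filter3d(diff, params$mean_filter_size)
  thr <- li_threshold(diff, exclude_zero = params$exclude_zero, mask = roi)
  thr <- max(as.numeric(thr), params$min_threshold_gray)
  sel <- diff$values >= thr
  if (!is.null(roi)) sel <- sel & roi$values
  out <- volume_grid(sel, voxel_um = pair$low$voxel_um, semantics = "binary")
  attr(out, "threshold") <- as.numeric(thr)
  attr(out, "difference") <- diff
  out
}

#' Segment regenerated bone from the sub-edge volume
#'
#' The original 17.9-keV volume is smoothed with a 3x3x3 average, converted
#' to attenuation, and every extravascular voxel at or above the bone
#' threshold (default 4.74 /cm, i.e. about 500 mg/cm^3 hydroxyapatite) is
#' classified as bone.
#'
#' @param low Sub-edge (17.9 keV) gray [volume_grid], registered.
#' @param vessels Binary vascular mask on the same lattice (excluded from
#'   bone).
#' @param cal A [calibration_line].
#' @param params A [segmentation_params].
#' @param roi Optional binary [volume_grid] restricting the output.
#' @return Binary [volume_grid] of bone voxels; attribute `mu` holds the
#'   smoothed attenuation volume.
#' @export
segment_bone <- function(low, vessels, cal = calibration_line(),
                         params = segmentation_params(), roi = NULL) {
  stopifnot_same_lattice(low, vessels)
  sm <- mean_filter3d(low, params$mean_filter_size)
  mu <- gray_to_mu(sm, cal)
  sel <- mu$values >= params$bone_mu_threshold & !vessels$values
  if (!is.null(roi)) sel <- sel & roi$values
  out <- volume_grid(sel, voxel_um = low$voxel_um, semantics = "binary")
  attr(out, "mu") <- mu
  out
}
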