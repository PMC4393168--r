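#' Hydroxyapatite-density distribution of segmented bone
#'
#' Converts the (3x3x3-averaged) sub-edge volume to d.HAp through the
#' calibration line and histograms the bone voxels in fixed-width bins
#' anchored at the mineralization floor (default 8 mg/cm^3 bins starting at
#' 500), expressing each bin as a percentage of all bone voxels. The mean
#' and median are computed from the raw per-voxel values.
#'
#' @param bone_mask Binary [volume_grid] of bone voxels.
#' @param low Sub-edge (17.9 keV) gray [volume_grid].
#' @param cal A [calibration_line].
#' @param roi Optional binary ROI [volume_grid] restricting the analysis.
#' @param bin_width_dhap Bin width, mg/cm^3.
#' @param origin_dhap Left edge of the first bin, mg/cm^3.
#' @param mean_filter_size Averaging filter applied to `low` before
#'   conversion (odd; 0 or 1 disables).
#' @return An object of class `density_histogram`: data.frame `bins`
#'   (`bin_left`, `bin_right`, `percent`), `mean_dhap`, `median_dhap`,
#'   `n_voxels`; or a histogram with `n_voxels = 0` and `NA` summaries for
#'   an empty mask.
#' @export
dhap_distribution <- function(bone_mask, low, cal = calibration_line(),
                              roi = NULL, bin_width_dhap = 8,
                              origin_dhap = 500, mean_filter_size = 3L) {
  stopifnot_same_lattice(bone_mask, low)
  sel <- bone_mask$values
  if (!is.null(roi)) sel <- sel & roi$values
  sm <- if (mean_filter_size > 1) mean_filter3d(low, mean_filter_size) else low
  dh <- mu_to_dhap(gray_to_mu(sm$values[sel], cal), cal)
  if (length(dh) == 0) {
    return(structure(list(
      bins = data.frame(bin_left = numeric(0), bin_right = numeric(0),
                        percent = numeric(0)),
      mean_dhap = NA_real_, median_dhap = NA_real_, n_voxels = 0L,
      bin_width = bin_width_dhap, origin = origin_dhap),
      class = "density_histogram"))
  }
  lo_edge <- origin_dhap + bin_width_dhap *
    floor((min(dh) - origin_dhap) / bin_width_dhap)
  hi_edge <- origin_dhap + bin_width_dhap *
    ceiling((max(dh) - origin_dhap) / bin_width_dhap + 1e-9)
  if (hi_edge <= lo_edge) hi_edge <- lo_edge + bin_width_dhap
  edges <- seq(lo_edge, hi_edge, by = bin_width_dhap)
  idx <- findInterval(dh, edges, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > length(edges) - 1L] <- length(edges) - 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(
    bins = data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
                      percent = 100 * counts / length(dh)),
    mean_dhap = mean(dh), median_dhap = stats::median(dh),
    n_voxels = length(dh),
    bin_width = bin_width_dhap, origin = origin_dhap),
    class = "density_histogram")
}

#' @export
print.density_histogram <- function(x, ...) {
  cat(sprintf("<density_histogram> %d voxels, mean %.1f, median %.1f mg/cm^3 (bin %g)\n",
              x$n_voxels, x$mean_dhap, x$median_dhap, x$bin_width))
  invisible(x)
}

#' Average per-specimen density histograms within a group
#'
#' Aligns histograms on a common bin grid and averages the per-specimen
#' percentages (each specimen weighted equally, matching a mean +/- SEM
#' presentation); pooling all voxels instead is available via
#' `pooled = TRUE`, which weights specimens by their voxel counts.
#'
#' @param hists List of `density_histogram` objects.
#' @param pooled Weight specimens by voxel count instead of equally.
#' @return A data.frame `bin_left`, `bin_right`, `percent`, `sem`.
#' @export
average_dhap_histograms <- function(hists, pooled = FALSE) {
  hists <- Filter(function(h) h$n_voxels > 0, hists)
  if (length(hists) == 0)
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      percent = numeric(0), sem = numeric(0)))
  bw <- hists[[1]]$bin_width
  lo <- min(vapply(hists, function(h) min(h$bins$bin_left), 0))
  hi <- max(vapply(hists, function(h) max(h$bins$bin_right), 0))
  edges <- seq(lo, hi, by = bw)
  mat <- vapply(hists, function(h) {
    p <- numeric(length(edges) - 1)
    i <- round((h$bins$bin_left - lo) / bw) + 1L
    p[i] <- h$bins$percent
    p
  }, numeric(length(edges) - 1))
  mat <- matrix(mat, nrow = length(edges) - 1)
  if (pooled) {
    w <- vapply(hists, function(h) h$n_voxels, 0)
    avg <- as.numeric(mat %*% (w / sum(w)))
  } else {
    avg <- rowMeans(mat)
  }
  sem <- apply(mat, 1, stats::sd) / sqrt(ncol(mat))
  data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
             percent = avg, sem = sem)
}
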