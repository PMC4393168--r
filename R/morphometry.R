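#' Local thickness field
#'
#' For every foreground voxel, the diameter of the largest sphere that fits
#' entirely inside the foreground and covers that voxel (distance-ridge
#' method: exact Euclidean distance transform, reduction to maximal-ball
#' centers, then sphere painting). This is the local diameter used both for
#' the mean vessel diameter V.D (sampled on the skeleton) and the bone
#' thickness B.Th (averaged over the structure).
#'
#' Diameters follow the usual digital convention `2 * dt`, with `dt` the
#' distance from a maximal-ball center to the nearest background voxel
#' center: a tube rasterized at nominal diameter `d` voxels measures about
#' `d`, and an isolated voxel measures 2 voxel widths.
#'
#' @param mask Binary [volume_grid] (or logical array).
#' @return A [volume_grid] (semantics `"mu"`-free numeric) of local
#'   diameters in micrometers, 0 on the background; for a plain array
#'   input, diameters in voxel units.
#' @export
local_thickness <- function(mask) {
  if (inherits(mask, "volume_grid")) {
    th <- local_thickness_cpp(as.logical(mask$values), as.integer(dim(mask$values)))
    out <- mask
    out$values <- array(th * mask$voxel_um, dim(mask$values))
    out$semantics <- "gray" # plain scalar field; unit um recorded in docs
    return(out)
  }
  array(local_thickness_cpp(as.logical(mask), as.integer(dim(mask))), dim(mask))
}

#' Skeletonize a binary structure
#'
#' Homotopy-preserving 3D curve thinning (26-connected foreground,
#' 6-connected background; iterative sequential removal of simple border
#' points over 6 directional sub-iterations, preserving curve endpoints),
#' followed by graph extraction: per-voxel degree under 26-connectivity,
#' node clusters (degree >= 3), free ends (degree 1), and maximal
#' node-to-node / node-to-free-end segments. Spurs - free-end segments
#' hanging off a node with fewer than `prune_spur_vox` own voxels, a known
#' thinning artifact - are pruned and segments re-extracted.
#'
#' @param mask Binary [volume_grid].
#' @param prune_spur_vox Minimum own-voxel count for a node-to-free-end
#'   segment to survive pruning (default 2).
#' @return An object of class `skeleton`: the skeleton volume, per-voxel
#'   degree, the segment list (1-based linear voxel indices), terminus
#'   codes, and counts of nodes and free ends.
#' @export
skeletonize <- function(mask, prune_spur_vox = 2L) {
  stopifnot(inherits(mask, "volume_grid"))
  d <- dim(mask$values)
  sk <- thin3d_cpp(as.logical(mask$values), as.integer(d), 1000L)
  gr <- skeleton_segments_cpp(sk, as.integer(d))
  # prune spurs: node-to-free-end segments shorter than the cutoff
  spur <- (pmin(gr$end1, gr$end2) == 0L & pmax(gr$end1, gr$end2) == 1L) &
    gr$n_vox < prune_spur_vox
  if (any(spur)) {
    drop_vox <- unlist(gr$voxels[spur], use.names = FALSE)
    sk[drop_vox] <- FALSE
    gr <- skeleton_segments_cpp(sk, as.integer(d))
  }
  deg <- gr$degree
  structure(list(
    skeleton = volume_grid(array(sk, d), voxel_um = mask$voxel_um,
                           semantics = "binary"),
    degree = array(deg, d),
    segments = gr$voxels,
    end_types = cbind(end1 = gr$end1, end2 = gr$end2),
    n_segments = length(gr$voxels),
    n_nodes = gr$n_node_clusters,
    n_free_ends = sum(deg == 1L, na.rm = TRUE),
    voxel_um = mask$voxel_um,
    prune_spur_vox = as.integer(prune_spur_vox)
  ), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d voxels, %d segments, %d nodes, %d free ends\n",
              sum(x$skeleton$values), x$n_segments, x$n_nodes, x$n_free_ends))
  invisible(x)
}

#' Volume fraction of a structure within an ROI
#'
#' @param mask Binary [volume_grid] of the structure.
#' @param roi Binary [volume_grid] of the region of interest (nonempty).
#' @return Percent of ROI voxels occupied by the structure.
#' @export
volume_fraction <- function(mask, roi) {
  stopifnot_same_lattice(mask, roi)
  n_roi <- sum(roi$values)
  if (n_roi == 0) stop("empty ROI")
  100 * sum(mask$values & roi$values) / n_roi
}

#' Mean skeleton (vessel) diameter
#'
#' V.D: the unweighted mean of the local diameter over all skeleton voxels.
#'
#' @param skel A [skeleton].
#' @param thickness Local thickness [volume_grid] in micrometers from
#'   [local_thickness()] of the same mask.
#' @return Mean diameter in micrometers; `NA` for an empty skeleton.
#' @export
mean_skeleton_diameter <- function(skel, thickness) {
  stopifnot(inherits(skel, "skeleton"))
  sel <- skel$skeleton$values
  if (!any(sel)) return(NA_real_)
  mean(thickness$values[sel])
}

#' Mean structure thickness
#'
#' B.Th: the mean local thickness over all structure (foreground) voxels,
#' i.e. the structure-volume-weighted mean diameter.
#'
#' @param mask Binary [volume_grid].
#' @param thickness Optional precomputed [local_thickness()] field.
#' @return Mean thickness in micrometers; `NA` for an empty mask.
#' @export
mean_structure_thickness <- function(mask, thickness = NULL) {
  if (!any(mask$values)) return(NA_real_)
  if (is.null(thickness)) thickness <- local_thickness(mask)
  mean(thickness$values[mask$values])
}

#' Segment density
#'
#' Number of node-to-node or node-to-free-end segments per cubic millimeter
#' of ROI.
#'
#' @param skel A [skeleton] (computed on the ROI-restricted mask).
#' @param roi_volume_mm3 ROI volume in mm^3 (> 0).
#' @return Segments per mm^3.
#' @export
segment_density <- function(skel, roi_volume_mm3) {
  if (roi_volume_mm3 <= 0) stop("ROI volume must be positive")
  skel$n_segments / roi_volume_mm3
}

#' Vessel diameter classes
#'
#' The five half-open diameter divisions (micrometers) used for
#' vessel-size-specific quantities: <10, [10,20), [20,30), [30,40), >=40.
#'
#' @return Numeric vector of bin edges `c(0, 10, 20, 30, 40, Inf)` with a
#'   `labels` attribute.
#' @export
diameter_bins <- function() {
  edges <- c(0, 10, 20, 30, 40, Inf)
  attr(edges, "labels") <- c("<10", "10-20", "20-30", "30-40", ">40")
  edges
}

#' Vessel-size-specific volume fractions and segment densities
#'
#' Each skeleton segment is assigned a diameter (mean local diameter over
#' its own skeleton voxels) and thereby one of the five diameter classes;
#' each foreground voxel is assigned to the class of the segment owning its
#' geodesically nearest skeleton voxel (multi-source breadth-first
#' propagation through the mask). Per-class V.Vf and V.Seg therefore
#' partition the totals exactly.
#'
#' @param skel A [skeleton] of `mask`.
#' @param mask Binary [volume_grid] the skeleton came from (ROI-restricted).
#' @param roi Binary ROI [volume_grid].
#' @param thickness Local thickness field from [local_thickness()] on
#'   `mask`, micrometers.
#' @param bins Bin edges, default [diameter_bins()].
#' @return A data.frame with columns `bin`, `diameter_lo`, `diameter_hi`,
#'   `vvf_pct`, `seg_per_mm3`, `n_segments`, `n_voxels`.
#' @export
size_specific <- function(skel, mask, roi, thickness, bins = diameter_bins()) {
  stopifnot(inherits(skel, "skeleton"))
  stopifnot_same_lattice(mask, roi)
  labels <- attr(bins, "labels")
  nb <- length(bins) - 1L
  roi_vol <- roi_volume_mm3(roi)
  n_roi <- sum(roi$values)
  if (n_roi == 0) stop("empty ROI")

  nseg <- skel$n_segments
  out <- data.frame(bin = labels,
                    diameter_lo = bins[-length(bins)], diameter_hi = bins[-1],
                    vvf_pct = 0, seg_per_mm3 = 0,
                    n_segments = 0L, n_voxels = 0L)
  if (nseg == 0L) return(out)

  seg_diam <- vapply(skel$segments, function(v) {
    if (length(v) == 0L) return(NA_real_)
    mean(thickness$values[v])
  }, 0)
  # segments with no own voxels (rare thick-junction bridges): overall mean
  seg_diam[is.na(seg_diam)] <- mean(seg_diam, na.rm = TRUE)
  seg_bin <- findInterval(seg_diam, bins, rightmost.closed = FALSE)
  seg_bin[seg_bin < 1L] <- 1L
  seg_bin[seg_bin > nb] <- nb

  # voxel ownership: propagate segment ids outward from skeleton voxels
  seed_idx <- unlist(skel$segments, use.names = FALSE)
  seed_lab <- rep.int(seq_len(nseg), lengths(skel$segments))
  lab <- propagate_labels_cpp(as.logical(mask$values), as.integer(dim(mask$values)),
                              as.integer(seed_idx), as.integer(seed_lab))
  fg <- which(mask$values & roi$values)
  vl <- lab[fg]
  if (any(vl == 0L)) {
    # foreground disconnected from every skeleton voxel: nearest segment
    warning(sum(vl == 0L), " foreground voxels had no skeleton; assigned to nearest segment")
    d <- dim(mask$values)
    un <- fg[vl == 0L]
    co <- arrayInd(un, d)
    seed_co <- arrayInd(seed_idx, d)
    for (i in seq_along(un)) {
      dd <- colSums((t(seed_co) - co[i, ])^2)
      vl[which(fg == un[i])] <- seed_lab[which.min(dd)]
    }
  }
  vox_bin <- seg_bin[vl]
  for (b in seq_len(nb)) {
    segs_b <- sum(seg_bin == b)
    vox_b <- sum(vox_bin == b)
    out$vvf_pct[b] <- 100 * vox_b / n_roi
    out$seg_per_mm3[b] <- segs_b / roi_vol
    out$n_segments[b] <- segs_b
    out$n_voxels[b] <- vox_b
  }
  out
}

#' Full morphometry of vascular and bone masks
#'
#' Computes the six structural indices - V.Vf, V.D, V.Seg, B.Vf, B.Th,
#' B.Seg - plus vessel-size-specific V.Vf and V.Seg for the five diameter
#' classes, all within the given ROI. Masks are intersected with the ROI
#' before skeletonization so segment counts refer to the analysis cylinder.
#'
#' @param vessel_mask,bone_mask Binary [volume_grid] masks.
#' @param roi Binary ROI [volume_grid] (from [roi_mask()]).
#' @param prune_spur_vox Spur-pruning cutoff passed to [skeletonize()].
#' @return An object of class `morphometry_result`: a list with elements
#'   `vvf_pct`, `vd_um`, `vseg_per_mm3`, `bvf_pct`, `bth_um`,
#'   `bseg_per_mm3`, `per_bin` (data.frame), `roi_volume_mm3`, and a
#'   `details` list (skeletons, thickness fields).
#' @export
morphometry <- function(vessel_mask, bone_mask, roi, prune_spur_vox = 2L) {
  stopifnot_same_lattice(vessel_mask, roi)
  stopifnot_same_lattice(bone_mask, roi)
  vx <- roi$voxel_um
  roi_vol <- roi_volume_mm3(roi)

  vmask <- volume_grid(vessel_mask$values & roi$values, vx, "binary")
  bmask <- volume_grid(bone_mask$values & roi$values, vx, "binary")
  if (any(vmask$values & bmask$values))
    stop("vessel and bone masks overlap")

  empty_bins <- {
    bins <- diameter_bins()
    data.frame(bin = attr(bins, "labels"),
               diameter_lo = bins[-length(bins)], diameter_hi = bins[-1],
               vvf_pct = 0, seg_per_mm3 = 0, n_segments = 0L, n_voxels = 0L)
  }

  if (any(vmask$values)) {
    vth <- local_thickness(vmask)
    vskel <- skeletonize(vmask, prune_spur_vox)
    vvf <- volume_fraction(vmask, roi)
    vd <- mean_skeleton_diameter(vskel, vth)
    vseg <- segment_density(vskel, roi_vol)
    per_bin <- size_specific(vskel, vmask, roi, vth)
  } else {
    vth <- NULL; vskel <- NULL
    vvf <- 0; vd <- NA_real_; vseg <- 0
    per_bin <- empty_bins
  }

  if (any(bmask$values)) {
    bth_field <- local_thickness(bmask)
    bskel <- skeletonize(bmask, prune_spur_vox)
    bvf <- volume_fraction(bmask, roi)
    bth <- mean_structure_thickness(bmask, bth_field)
    bseg <- segment_density(bskel, roi_vol)
  } else {
    bskel <- NULL
    bvf <- 0; bth <- NA_real_; bseg <- 0
  }

  structure(list(vvf_pct = vvf, vd_um = vd, vseg_per_mm3 = vseg,
                 bvf_pct = bvf, bth_um = bth, bseg_per_mm3 = bseg,
                 per_bin = per_bin, roi_volume_mm3 = roi_vol,
                 details = list(vessel_skeleton = vskel, bone_skeleton = bskel,
                                vessel_thickness = vth)),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  V.Vf %6.2f %%   V.D  %6.2f um   V.Seg %8.1f /mm^3\n",
              x$vvf_pct, x$vd_um, x$vseg_per_mm3))
  cat(sprintf("  B.Vf %6.2f %%   B.Th %6.2f um   B.Seg %8.1f /mm^3\n",
              x$bvf_pct, x$bth_um, x$bseg_per_mm3))
  cat(sprintf("  ROI volume: %.4f mm^3\n", x$roi_volume_mm3))
  cat("  size-specific:\n")
  print(x$per_bin[, c("bin", "vvf_pct", "seg_per_mm3")], row.names = FALSE)
  invisible(x)
}

#' One-row data.frame of a morphometry result
#'
#' Flattens a [morphometry()] result into a single row (all indices plus
#' per-bin columns), the per-specimen record used by [run_study()].
#'
#' @param x A `morphometry_result`.
#' @return A one-row data.frame.
#' @export
as_morphometry_row <- function(x) {
  stopifnot(inherits(x, "morphometry_result"))
  row <- data.frame(vvf_pct = x$vvf_pct, vd_um = x$vd_um,
                    vseg_per_mm3 = x$vseg_per_mm3, bvf_pct = x$bvf_pct,
                    bth_um = x$bth_um, bseg_per_mm3 = x$bseg_per_mm3,
                    roi_volume_mm3 = x$roi_volume_mm3)
  keys <- c("lt10", "10to20", "20to30", "30to40", "ge40")
  for (i in seq_len(nrow(x$per_bin))) {
    row[[paste0("vvf_", keys[i])]] <- x$per_bin$vvf_pct[i]
    row[[paste0("vseg_", keys[i])]] <- x$per_bin$seg_per_mm3[i]
  }
  row
}
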