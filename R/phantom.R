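#' Synthetic dual-energy phantom specification
#'
#' Describes a synthetic specimen emulating a contrast-perfused drill-hole
#' defect: a cylindrical analysis region containing a tubular vessel
#' network whose attenuation jumps across the contrast agent's K-edge,
#' bone regions whose attenuation is energy-independent between 17.9 and
#' 18.1 keV, partial-volume blur, additive gray-level noise, and a small
#' rigid misalignment between the two energy acquisitions.
#'
#' Defaults reproduce the imaging conditions the pipeline is designed for:
#' 2.74 um cubic voxels, a 720 x 300 um analysis cylinder, strong vascular
#' contrast at the supra-edge energy (6 vs 60 /cm), a cortical shell around
#' the drill hole at 1364 mg/cm^3 hydroxyapatite plus regenerated-bone
#' blobs at 800 mg/cm^3 inside the defect, one-voxel Gaussian blur, 2
#' gray-level noise, and a misalignment of a few voxels.
#'
#' @param roi_diameter_um,roi_height_um,voxel_um ROI cylinder geometry and
#'   voxel size (micrometers).
#' @param margin_vox Lattice padding around the ROI, voxels.
#' @param vessel_segments `NULL` to grow a random vessel forest (see
#'   [random_vessel_tree()]), or a data.frame with columns `p1x..p2z`
#'   (micrometers), `radius_um`, `tree`, `edge`.
#' @param vessel_args List of arguments for [random_vessel_tree()] used when
#'   `vessel_segments` is `NULL` (e.g. `list(n_trees = 4)`).
#' @param bone_regions `NULL` for the default cortical shell plus
#'   regenerated-bone spheres, `list()` for no bone, or a list of
#'   [bone_region()] primitives.
#' @param mu_vessel_low,mu_vessel_high Vessel attenuation (/cm) at 17.9 and
#'   18.1 keV; the supra-edge value must exceed the sub-edge value.
#' @param mu_background Soft-tissue/marrow attenuation (/cm), both energies.
#' @param dhap_cortical,dhap_regenerated Bone densities (mg/cm^3) of the
#'   default cortical shell and defect bone.
#' @param target_bvf_pct Approximate regenerated-bone volume fraction the
#'   default bone generator aims for inside the ROI.
#' @param blur_sigma_um Gaussian PSF sigma (micrometers), identical at both
#'   energies; 0 disables blur.
#' @param noise_sd_gray Additive Gaussian noise SD in gray levels; 0
#'   disables noise.
#' @param misalignment A [rigid_transform] applied to the sub-edge volume
#'   (translations in voxels, small rotations in degrees).
#' @param cal A [calibration_line] for the gray/mu/d.HAp conversions.
#' @param seed Integer seed fixing the generated volumes bit-exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(roi_diameter_um = 720, roi_height_um = 300,
                         voxel_um = 2.74, margin_vox = 8L,
                         vessel_segments = NULL, vessel_args = list(),
                         bone_regions = NULL,
                         mu_vessel_low = 6, mu_vessel_high = 60,
                         mu_background = 0.8,
                         dhap_cortical = 1364, dhap_regenerated = 800,
                         target_bvf_pct = 28,
                         blur_sigma_um = 2.74, noise_sd_gray = 2,
                         misalignment = rigid_transform(c(1.5, -2.5, 1.0),
                                                        c(0.3, 0, 0)),
                         cal = calibration_line(), seed = 1L) {
  if (mu_vessel_high <= mu_vessel_low)
    stop("mu_vessel_high must exceed mu_vessel_low (K-edge jump)")
  if (roi_diameter_um <= 0 || roi_height_um <= 0 || voxel_um <= 0)
    stop("ROI geometry must be positive")
  if (!is.null(vessel_segments) && nrow(vessel_segments) > 0 &&
      any(vessel_segments$radius_um <= 0))
    stop("vessel radii must be positive")
  spec <- structure(list(
    roi_diameter_um = roi_diameter_um, roi_height_um = roi_height_um,
    voxel_um = voxel_um, margin_vox = as.integer(margin_vox),
    vessel_segments = vessel_segments, vessel_args = vessel_args,
    bone_regions = bone_regions,
    mu_vessel_low = mu_vessel_low, mu_vessel_high = mu_vessel_high,
    mu_background = mu_background,
    dhap_cortical = dhap_cortical, dhap_regenerated = dhap_regenerated,
    target_bvf_pct = target_bvf_pct,
    blur_sigma_um = blur_sigma_um, noise_sd_gray = noise_sd_gray,
    misalignment = misalignment, cal = cal, seed = as.integer(seed)),
    class = "phantom_spec")
  spec
}

phantom_dims <- function(spec) {
  m <- spec$margin_vox
  c(ceiling(spec$roi_height_um / spec$voxel_um) + 2L * m,
    ceiling(spec$roi_diameter_um / spec$voxel_um) + 2L * m,
    ceiling(spec$roi_diameter_um / spec$voxel_um) + 2L * m)
}

#' ROI specification matching a phantom
#'
#' @param spec A [phantom_spec].
#' @return An [roi_spec] centered in the phantom lattice.
#' @export
phantom_roi <- function(spec) {
  roi_spec(center = (phantom_dims(spec) + 1) / 2,
           diameter_um = spec$roi_diameter_um,
           height_um = spec$roi_height_um, axis = 1L)
}

#' Bone shape primitive
#'
#' @param type `"sphere"`, `"slab"`, `"tube"` or `"shell"` (a hollow
#'   cylinder along a lattice axis).
#' @param dhap Hydroxyapatite density of the primitive, mg/cm^3.
#' @param ... Geometry in micrometers (lattice coordinates): sphere
#'   `center`, `radius`; slab `lo`, `hi` (length-3 corners); tube `p1`,
#'   `p2`, `radius`; shell `center`, `inner_radius`, `outer_radius`,
#'   `height` (`Inf` for full extent), `axis`.
#' @return A `bone_region` list.
#' @export
bone_region <- function(type = c("sphere", "slab", "tube", "shell"), dhap, ...) {
  type <- match.arg(type)
  structure(c(list(type = type, dhap = dhap), list(...)), class = "bone_region")
}

# voxel centers in lattice micrometers along each axis
axis_coords_um <- function(d, voxel_um) {
  lapply(d, function(n) (seq_len(n) - 0.5) * voxel_um)
}

# linear indices of a logical sub-box placed at 1-based offsets
subbox_lin <- function(sub, idx, d) {
  w <- which(sub, arr.ind = TRUE)
  if (nrow(w) == 0) return(integer(0))
  (idx[[1]][w[, 1]]) +
    (idx[[2]][w[, 2]] - 1L) * d[1] +
    (idx[[3]][w[, 3]] - 1L) * d[1] * d[2]
}

rasterize_bone_regions <- function(regions, d, voxel_um) {
  dhap <- array(0, d)
  mask <- array(FALSE, d)
  co <- axis_coords_um(d, voxel_um)
  for (rg in regions) {
    lin <- switch(rg$type,
      sphere = {
        lo <- pmax(1L, as.integer(floor((rg$center - rg$radius) / voxel_um)))
        hi <- pmin(d, as.integer(ceiling((rg$center + rg$radius) / voxel_um)) + 1L)
        if (any(lo > hi)) integer(0) else {
          idx <- lapply(1:3, function(a) lo[a]:hi[a])
          r2 <- outer(outer((co[[1]][idx[[1]]] - rg$center[1])^2,
                            (co[[2]][idx[[2]]] - rg$center[2])^2, `+`),
                      (co[[3]][idx[[3]]] - rg$center[3])^2, `+`)
          subbox_lin(r2 <= rg$radius^2, idx, d)
        }
      },
      slab = {
        idx <- lapply(1:3, function(a)
          which(co[[a]] >= rg$lo[a] & co[[a]] <= rg$hi[a]))
        if (any(lengths(idx) == 0)) integer(0) else
          subbox_lin(array(TRUE, lengths(idx)), idx, d)
      },
      tube = {
        seg <- matrix(c(rg$p1 / voxel_um - 0.5, rg$p2 / voxel_um - 0.5,
                        rg$radius / voxel_um), nrow = 1)
        which(rasterize_tubes_cpp(as.integer(d), seg))
      },
      shell = {
        ax <- if (is.null(rg$axis)) 1L else rg$axis
        perp <- setdiff(1:3, ax)
        ctr <- rg$center
        h <- if (is.null(rg$height)) Inf else rg$height
        rr <- outer((co[[perp[1]]] - ctr[perp[1]])^2,
                    (co[[perp[2]]] - ctr[perp[2]])^2, `+`)
        ann <- rr >= rg$inner_radius^2 & rr <= rg$outer_radius^2
        in_ax <- which(abs(co[[ax]] - ctr[ax]) <= h / 2)
        sub <- array(FALSE, c(length(in_ax), dim(ann)))
        for (i in seq_along(in_ax)) sub[i, , ] <- ann
        idx <- vector("list", 3)
        idx[[ax]] <- in_ax
        idx[[perp[1]]] <- seq_len(d[perp[1]])
        idx[[perp[2]]] <- seq_len(d[perp[2]])
        sub <- aperm(sub, order(c(ax, perp)))
        subbox_lin(sub, idx, d)
      })
    if (length(lin) == 0) next
    clash <- mask[lin] & dhap[lin] != rg$dhap
    if (any(clash))
      stop("overlapping bone primitives with contradictory densities")
    dhap[lin] <- rg$dhap
    mask[lin] <- TRUE
  }
  list(mask = mask, dhap = dhap)
}

#' Grow a random vessel forest
#'
#' Random binary trees of tapering tubes confined to the ROI cylinder:
#' each branch splits into two children with diameter multiplied by
#' U(0.7, 0.95) until the tree reaches `max_depth` or the diameter falls
#' below `min_diameter_um`; edges leaving the ROI are clipped and
#' terminated. Every internal vertex has exactly two children, so the
#' number of skeleton segments of the rasterized network equals the number
#' of generated edges.
#'
#' @param spec A [phantom_spec] (for ROI geometry).
#' @param n_trees Number of independent trees.
#' @param root_diameter_um Root branch diameter.
#' @param mean_edge_um Mean edge length.
#' @param branch_angle_deg Mean half-angle between children.
#' @param max_depth Maximum branching depth.
#' @param min_diameter_um Diameter below which a branch stops.
#' @return A data.frame of edges: `p1x p1y p1z p2x p2y p2z` (micrometers),
#'   `radius_um`, `tree`, `edge`, `depth`.
#' @export
random_vessel_tree <- function(spec, n_trees = 6L, root_diameter_um = 48,
                               mean_edge_um = 70, branch_angle_deg = 32,
                               max_depth = 5L, min_diameter_um = 7) {
  d <- phantom_dims(spec)
  ctr <- c((d[1] + 1) / 2, (d[2] + 1) / 2, (d[3] + 1) / 2) * spec$voxel_um -
    spec$voxel_um / 2
  roi_r <- spec$roi_diameter_um / 2
  roi_h <- spec$roi_height_um
  z_lo <- ctr[1] - roi_h / 2
  z_hi <- ctr[1] + roi_h / 2

  # branch centerlines keep one tube radius clear of the ROI wall so the
  # rasterized surface stays inside the analysis cylinder radially
  inside_roi <- function(p, r) {
    p[1] >= z_lo && p[1] <= z_hi &&
      (p[2] - ctr[2])^2 + (p[3] - ctr[3])^2 <= (roi_r - r)^2
  }
  # clip p1->p2 to the shrunk ROI cylinder (p1 assumed inside)
  clip_end <- function(p1, p2, r) {
    if (inside_roi(p2, r)) return(list(p = p2, clipped = FALSE))
    lo <- 0; hi <- 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (inside_roi(p1 + mid * (p2 - p1), r)) lo <- mid else hi <- mid
    }
    list(p = p1 + lo * (p2 - p1), clipped = TRUE)
  }
  rand_perp <- function(u) {
    v <- c(-u[2], u[1], 0)
    if (sqrt(sum(v^2)) < 1e-6) v <- c(0, -u[3], u[2])
    v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    phi <- stats::runif(1, 0, 2 * pi)
    cos(phi) * v + sin(phi) * w
  }

  rows <- list()
  edge_id <- 0L
  for (tr in seq_len(n_trees)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * max(roi_r - root_diameter_um / 2, 0) * 0.6
    p0 <- c(z_lo + 1e-6,
            ctr[2] + rad * cos(ang), ctr[3] + rad * sin(ang))
    queue <- list(list(p = p0, dir = c(1, 0, 0), diam = root_diameter_um,
                       depth = 0L))
    while (length(queue) > 0) {
      br <- queue[[1]]; queue <- queue[-1]
      len <- max(20, stats::rnorm(1, mean_edge_um, mean_edge_um / 4))
      # jitter direction slightly
      jit <- rand_perp(br$dir) * tan(stats::runif(1, 0, 10) * pi / 180)
      dir <- br$dir + jit
      dir <- dir / sqrt(sum(dir^2))
      p2_try <- br$p + dir * len
      cl <- clip_end(br$p, p2_try, br$diam / 2)
      seg_len <- sqrt(sum((cl$p - br$p)^2))
      if (seg_len < spec$voxel_um) next
      edge_id <- edge_id + 1L
      rows[[edge_id]] <- data.frame(
        p1x = br$p[1], p1y = br$p[2], p1z = br$p[3],
        p2x = cl$p[1], p2y = cl$p[2], p2z = cl$p[3],
        radius_um = br$diam / 2, tree = tr, edge = edge_id,
        depth = br$depth)
      if (cl$clipped || br$depth >= max_depth) next
      # branch into exactly two children
      for (ch in 1:2) {
        cd <- br$diam * stats::runif(1, 0.7, 0.95)
        if (cd < min_diameter_um) next
        theta <- stats::rnorm(1, branch_angle_deg, 6) * pi / 180
        perp <- rand_perp(dir)
        cdir <- cos(theta) * dir + sin(theta) * perp
        cdir <- cdir / sqrt(sum(cdir^2))
        queue[[length(queue) + 1L]] <- list(p = cl$p, dir = cdir, diam = cd,
                                            depth = br$depth + 1L)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(p1x = numeric(0), p1y = numeric(0), p1z = numeric(0),
                      p2x = numeric(0), p2y = numeric(0), p2z = numeric(0),
                      radius_um = numeric(0), tree = integer(0),
                      edge = integer(0), depth = integer(0)))
  do.call(rbind, rows)
}

# distance from point to each segment (rows of seg data.frame), um
point_segment_dist <- function(p, segs) {
  a <- cbind(segs$p1x, segs$p1y, segs$p1z)
  b <- cbind(segs$p2x, segs$p2y, segs$p2z)
  ab <- b - a
  ap <- sweep(-a, 2, p, `+`)
  len2 <- rowSums(ab^2)
  t <- rowSums(ap * ab) / pmax(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  q <- a + ab * t
  sqrt(rowSums(sweep(-q, 2, p, `+`)^2))
}

default_bone_regions <- function(spec, vessel_segments) {
  d <- phantom_dims(spec)
  ctr_um <- (d + 1) / 2 * spec$voxel_um - spec$voxel_um / 2
  roi_r <- spec$roi_diameter_um / 2
  regions <- list(
    # cortical shell around the drill hole (outside the analysis cylinder)
    bone_region("shell", dhap = spec$dhap_cortical, center = ctr_um,
                inner_radius = roi_r + 4 * spec$voxel_um,
                outer_radius = roi_r + 4 * spec$voxel_um +
                  max(6 * spec$voxel_um, 0.08 * roi_r),
                height = Inf, axis = 1L))
  # regenerated-bone spheres inside the defect, avoiding the vessels
  roi_vol_um3 <- pi * roi_r^2 * spec$roi_height_um
  target_um3 <- spec$target_bvf_pct / 100 * roi_vol_um3
  placed_um3 <- 0
  attempts <- 0L
  r_range <- c(4.5 * spec$voxel_um, 9 * spec$voxel_um)
  while (placed_um3 < target_um3 && attempts < 20000L) {
    attempts <- attempts + 1L
    r <- stats::runif(1, r_range[1], r_range[2])
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * (roi_r - r)
    z <- stats::runif(1, ctr_um[1] - spec$roi_height_um / 2 + r,
                      ctr_um[1] + spec$roi_height_um / 2 - r)
    cen <- c(z, ctr_um[2] + rad * cos(ang), ctr_um[3] + rad * sin(ang))
    if (!is.null(vessel_segments) && nrow(vessel_segments) > 0) {
      dmin <- min(point_segment_dist(cen, vessel_segments) -
                    vessel_segments$radius_um)
      if (dmin < r + 1.5 * spec$voxel_um) next
    }
    regions[[length(regions) + 1L]] <-
      bone_region("sphere", dhap = spec$dhap_regenerated, center = cen,
                  radius = r)
    placed_um3 <- placed_um3 + 4 / 3 * pi * r^3
  }
  regions
}

#' Build a synthetic dual-energy specimen
#'
#' Rasterizes the phantom geometry into paired 8-bit sub-/supra-edge
#' volumes - vessels brighter at 18.1 keV by the K-edge jump, bone equally
#' bright at both energies - applies Gaussian partial-volume blur, the
#' specified rigid misalignment (to the sub-edge volume only), additive
#' gray noise, and 8-bit quantization. The returned ground truth (masks,
#' centerlines, per-edge radii) is untouched by blur, misalignment and
#' noise.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `pair` (a [dual_energy_pair]), `truth` (a
#'   `phantom_truth`: `vessel_mask`, `bone_mask`, `centerlines`,
#'   `per_segment_diameter_um`, `applied_misalignment`, `roi`), and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- phantom_dims(spec)
  vx <- spec$voxel_um

  segs <- spec$vessel_segments
  if (is.null(segs))
    segs <- do.call(random_vessel_tree, c(list(spec), spec$vessel_args))
  if (nrow(segs) > 0 && any(segs$radius_um < vx / 2)) {
    warning("vessel radius below half a voxel; rasterizing at least one voxel wide")
  }
  vessel_mask <- if (nrow(segs) > 0) {
    m <- matrix(c(segs$p1x / vx - 0.5, segs$p1y / vx - 0.5, segs$p1z / vx - 0.5,
                  segs$p2x / vx - 0.5, segs$p2y / vx - 0.5, segs$p2z / vx - 0.5,
                  segs$radius_um / vx), ncol = 7)
    mk <- array(rasterize_tubes_cpp(as.integer(d), m), d)
    # guarantee a one-voxel-wide line for sub-voxel radii
    thin <- which(segs$radius_um < vx / 2)
    for (s in thin) {
      p1 <- c(segs$p1x[s], segs$p1y[s], segs$p1z[s]) / vx + 0.5
      p2 <- c(segs$p2x[s], segs$p2y[s], segs$p2z[s]) / vx + 0.5
      n <- max(2L, ceiling(sqrt(sum((p2 - p1)^2)) / 0.4))
      pts <- cbind(seq(p1[1], p2[1], length.out = n),
                   seq(p1[2], p2[2], length.out = n),
                   seq(p1[3], p2[3], length.out = n))
      idx <- pmin(pmax(round(pts), 1), matrix(d, n, 3, byrow = TRUE))
      mk[idx] <- TRUE
    }
    mk
  } else array(FALSE, d)

  regions <- spec$bone_regions
  if (is.null(regions)) regions <- default_bone_regions(spec, segs)
  bone <- rasterize_bone_regions(regions, d, vx)
  if (any(bone$mask & vessel_mask))
    stop("vessel and bone primitives overlap with contradictory labels")

  # attenuation -> gray, per energy
  mu_bone <- dhap_to_mu(bone$dhap, spec$cal)
  mu_low <- array(spec$mu_background, d)
  mu_low[bone$mask] <- mu_bone[bone$mask]
  mu_high <- mu_low # bone and soft tissue: no edge between the two energies
  mu_low[vessel_mask] <- spec$mu_vessel_low
  mu_high[vessel_mask] <- spec$mu_vessel_high
  gray_low <- mu_to_gray(mu_low, spec$cal)
  gray_high <- mu_to_gray(mu_high, spec$cal)

  if (spec$blur_sigma_um > 0) {
    s <- spec$blur_sigma_um / vx
    gray_low <- array(gaussian_blur3d_cpp(gray_low, as.integer(d), s), d)
    gray_high <- array(gaussian_blur3d_cpp(gray_high, as.integer(d), s), d)
  }

  mis <- spec$misalignment
  misaligned <- any(mis$translation != 0) || any(mis$rotation_deg != 0)
  if (misaligned) {
    lowvg <- volume_grid(pmin(pmax(gray_low, 0), 255), vx, "gray")
    gray_low <- resample_volume(lowvg, mis)$values
  }

  quantize <- function(g) {
    if (spec$noise_sd_gray > 0)
      g <- g + stats::rnorm(length(g), 0, spec$noise_sd_gray)
    array(pmin(pmax(round(g), 0), 255), d)
  }
  low <- volume_grid(quantize(gray_low), vx, "gray")
  high <- volume_grid(quantize(gray_high), vx, "gray")

  truth <- structure(list(
    vessel_mask = volume_grid(vessel_mask, vx, "binary"),
    bone_mask = volume_grid(bone$mask, vx, "binary"),
    bone_dhap = bone$dhap,
    centerlines = segs,
    per_segment_diameter_um = if (nrow(segs) > 0) 2 * segs$radius_um else numeric(0),
    applied_misalignment = mis,
    roi = phantom_roi(spec),
    voxel_um = vx), class = "phantom_truth")

  list(pair = dual_energy_pair(low, high, transform = NULL),
       truth = truth, spec = spec)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d vessel edges, %d vessel voxels, %d bone voxels\n",
              nrow(x$centerlines), sum(x$vessel_mask$values),
              sum(x$bone_mask$values)))
  invisible(x)
}

#' Analytic indices from phantom ground truth
#'
#' Computes the six structural indices and the vessel-size-specific
#' quantities directly from the truth masks and centerlines, without any
#' segmentation, for scoring pipeline recovery. Vessel quantities come from
#' the generating edges (diameter = generated tube diameter, lengths
#' clipped to the ROI); bone thickness and segment counts are measured on
#' the truth bone mask itself.
#'
#' @param truth A `phantom_truth` from [build_phantom()].
#' @param roi An [roi_spec]; defaults to the phantom's own ROI.
#' @return A `morphometry_result` computed from ground truth.
#' @export
truth_indices <- function(truth, roi = truth$roi) {
  stopifnot(inherits(truth, "phantom_truth"))
  grid <- truth$vessel_mask
  rmask <- roi_mask(roi, grid)
  n_roi <- sum(rmask$values)
  if (n_roi == 0) stop("empty ROI")
  roi_vol <- roi_volume_mm3(rmask)

  vvf <- volume_fraction(truth$vessel_mask, rmask)
  bvf <- volume_fraction(truth$bone_mask, rmask)

  segs <- truth$centerlines
  bins <- diameter_bins()
  labels <- attr(bins, "labels")
  nb <- length(bins) - 1L
  per_bin <- data.frame(bin = labels,
                        diameter_lo = bins[-length(bins)], diameter_hi = bins[-1],
                        vvf_pct = 0, seg_per_mm3 = 0,
                        n_segments = 0L, n_voxels = NA_integer_)
  if (nrow(segs) > 0) {
    len <- sqrt((segs$p2x - segs$p1x)^2 + (segs$p2y - segs$p1y)^2 +
                  (segs$p2z - segs$p1z)^2)
    diam <- 2 * segs$radius_um
    vd <- sum(len * diam) / sum(len)
    vseg <- nrow(segs) / roi_vol
    sb <- findInterval(diam, bins, rightmost.closed = FALSE)
    sb[sb < 1L] <- 1L; sb[sb > nb] <- nb
    # analytic per-edge tube volumes, rescaled to the rasterized V.Vf so
    # the bin values partition the total exactly
    edge_vol <- pi * segs$radius_um^2 * len
    for (b in seq_len(nb)) {
      per_bin$n_segments[b] <- sum(sb == b)
      per_bin$seg_per_mm3[b] <- sum(sb == b) / roi_vol
      per_bin$vvf_pct[b] <- vvf * sum(edge_vol[sb == b]) / sum(edge_vol)
    }
  } else {
    vd <- NA_real_
    vseg <- 0
  }

  if (any(truth$bone_mask$values & rmask$values)) {
    bmask <- volume_grid(truth$bone_mask$values & rmask$values,
                         truth$voxel_um, "binary")
    bth <- mean_structure_thickness(bmask)
    bskel <- skeletonize(bmask)
    bseg <- segment_density(bskel, roi_vol)
  } else {
    bth <- NA_real_
    bseg <- 0
  }

  structure(list(vvf_pct = vvf, vd_um = vd, vseg_per_mm3 = vseg,
                 bvf_pct = bvf, bth_um = bth, bseg_per_mm3 = bseg,
                 per_bin = per_bin, roi_volume_mm3 = roi_vol,
                 details = list(source = "phantom_truth")),
            class = "morphometry_result")
}
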