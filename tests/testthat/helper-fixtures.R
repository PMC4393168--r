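# Fixture builders shared across tests. Everything is generated in code;
# sizes are kept small so the whole suite runs quickly.

# straight axis-1 tube mask of given diameter (voxels) in a lattice
make_tube_mask <- function(d = c(40, 25, 25), diameter_vox = 7,
                           center = c(ceiling(d[2] / 2), ceiling(d[3] / 2)),
                           voxel_um = 1) {
  seg <- matrix(c(1, center[1] - 1, center[2] - 1,
                  d[1] - 2, center[1] - 1, center[2] - 1,
                  diameter_vox / 2), nrow = 1)
  m <- array(kesct:::rasterize_tubes_cpp(as.integer(d), seg), d)
  volume_grid(m, voxel_um = voxel_um, semantics = "binary")
}

# digital ball of given diameter (voxels) centered on a voxel
make_ball_mask <- function(diameter_vox = 15, pad = 3, voxel_um = 1) {
  r <- diameter_vox / 2
  n <- diameter_vox + 2 * pad
  c0 <- pad + ceiling(diameter_vox / 2)
  co <- (1:n) - c0
  r2 <- outer(outer(co^2, co^2, `+`), co^2, `+`)
  volume_grid(array(r2 <= r^2, c(n, n, n)), voxel_um, "binary")
}

# well-separated binary tree of tubes (every internal vertex branches in 2):
# 7 edges -> 3 nodes, 5 free ends
make_tree_segments <- function() {
  mk <- function(p1, p2, r)
    data.frame(p1x = p1[1], p1y = p1[2], p1z = p1[3],
               p2x = p2[1], p2y = p2[2], p2z = p2[3],
               radius_um = r, tree = 1L, edge = NA_integer_)
  segs <- rbind(
    mk(c(10, 150, 150), c(80, 150, 150), 12),
    mk(c(80, 150, 150), c(150, 100, 150), 9),
    mk(c(80, 150, 150), c(150, 200, 150), 9),
    mk(c(150, 100, 150), c(220, 70, 110), 6),
    mk(c(150, 100, 150), c(220, 70, 190), 6),
    mk(c(150, 200, 150), c(220, 230, 110), 6),
    mk(c(150, 200, 150), c(220, 230, 190), 6))
  segs$edge <- seq_len(nrow(segs))
  segs
}

tree_phantom_spec <- function(..., segs = make_tree_segments()) {
  phantom_spec(roi_diameter_um = 290, roi_height_um = 230,
               vessel_segments = segs, bone_regions = list(),
               blur_sigma_um = 0, noise_sd_gray = 0,
               misalignment = rigid_transform(), seed = 1L, ...)
}

# small but realistic random phantom for end-to-end tests
small_phantom_spec <- function(..., seed = 3L) {
  phantom_spec(roi_diameter_um = 220, roi_height_um = 150, seed = seed, ...)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force largest-inscribed-sphere thickness oracle (small masks only)
brute_thickness <- function(mask) {
  m <- if (inherits(mask, "volume_grid")) mask$values else mask
  dm <- dim(m)
  fg <- which(m)
  bg <- which(!m)
  cof <- arrayInd(fg, dm)
  cob <- arrayInd(bg, dm)
  dt <- sqrt(vapply(seq_along(fg), function(i)
    min(colSums((t(cob) - cof[i, ])^2)), 0))
  th <- vapply(seq_along(fg), function(i) {
    cov <- sqrt(colSums((t(cof) - cof[i, ])^2)) <= dt - 0.5 + 1e-9
    max(2 * dt[cov])
  }, 0)
  out <- array(0, dm)
  out[fg] <- th
  out
}

# exhaustive scan of the Li cross-entropy criterion, independent of the
# package implementation: returns the criterion value for every split
brute_li_criterion <- function(x) {
  u <- sort(unique(x))
  vapply(u[-1], function(t) {
    b <- x[x < t]; a <- x[x >= t]
    -(sum(b) * log(mean(b)) + sum(a) * log(mean(a)))
  }, 0)
}
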