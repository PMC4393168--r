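#' Rigid transform between the two energy volumes
#'
#' A 6-parameter rigid-body transform: translations along the three array
#' axes (in voxels) and rotations about them (in degrees), applied about a
#' center of rotation. A point `p` (0-based voxel coordinates) maps to
#' `q = R (p - c) + c + t`, with the rotation matrix composed as
#' `R = R1(a1) R2(a2) R3(a3)` (rotation about axis 1 applied last).
#'
#' @param translation Numeric length 3, voxels.
#' @param rotation_deg Numeric length 3, degrees.
#' @param center Center of rotation, 0-based voxel coordinates; `NULL` means
#'   the lattice center is filled in when the transform is applied.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center = NULL) {
  stopifnot(length(translation) == 3L, length(rotation_deg) == 3L,
            all(is.finite(translation)), all(is.finite(rotation_deg)))
  structure(list(translation = as.numeric(translation),
                 rotation_deg = as.numeric(rotation_deg),
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.3f, %.3f, %.3f) vox, r = (%.3f, %.3f, %.3f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3]))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  r1 <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  r2 <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  r3 <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  r1 %*% r2 %*% r3
}

rotation_angles_deg <- function(R) {
  a2 <- asin(max(-1, min(1, R[1, 3])))
  a3 <- atan2(-R[1, 2], R[1, 1])
  a1 <- atan2(-R[2, 3], R[3, 3])
  c(a1, a2, a3) * 180 / pi
}

transform_center <- function(t, d) {
  if (!is.null(t$center)) t$center else (d - 1) / 2
}

# source-coordinate affine map (p_src = A p_out + b) for resampling with t
source_map <- function(t, d) {
  R <- rotation_matrix(t$rotation_deg)
  Rin <- t(R)
  ctr <- transform_center(t, d)
  b <- ctr - Rin %*% (ctr + t$translation)
  list(A = Rin, b = as.numeric(b))
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform].
#' @return The inverse [rigid_transform] (same center of rotation).
#' @export
invert_rigid <- function(t) {
  R <- rotation_matrix(t$rotation_deg)
  rigid_transform(translation = as.numeric(-t(R) %*% t$translation),
                  rotation_deg = rotation_angles_deg(t(R)),
                  center = t$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `t1` first, then `t2`
#' (both must share the same center of rotation).
#'
#' @param t1,t2 [rigid_transform] objects.
#' @return A [rigid_transform].
#' @export
compose_rigid <- function(t1, t2) {
  if (!identical(t1$center, t2$center))
    stop("transforms have different centers of rotation")
  R1 <- rotation_matrix(t1$rotation_deg)
  R2 <- rotation_matrix(t2$rotation_deg)
  rigid_transform(translation = as.numeric(R2 %*% t1$translation + t2$translation),
                  rotation_deg = rotation_angles_deg(R2 %*% R1),
                  center = t1$center)
}

#' Resample a volume through a rigid transform
#'
#' Trilinear interpolation on the same lattice; voxels mapped outside the
#' input lattice are filled with 0. The identity transform returns the
#' input bit-exactly.
#'
#' @param moving A [volume_grid].
#' @param t A [rigid_transform].
#' @return A resampled [volume_grid].
#' @export
resample_volume <- function(moving, t) {
  stopifnot(inherits(moving, "volume_grid"), inherits(t, "rigid_transform"))
  d <- dim(moving$values)
  sm <- source_map(t, d)
  vals <- resample_affine_cpp(as.numeric(moving$values), as.integer(d),
                              as.numeric(sm$A), sm$b)
  out <- moving
  out$values <- array(vals, d)
  if (moving$semantics == "binary")
    out$values <- array(out$values >= 0.5, d)
  out
}

mi_from_hist <- function(H) {
  n <- sum(H)
  if (n == 0) return(0)
  p <- H / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

mi_at <- function(fixed, moving, d, t, bins, stride, rng) {
  sm <- source_map(t, d)
  H <- joint_hist_cpp(fixed, moving, as.integer(d), as.numeric(sm$A), sm$b,
                      as.integer(bins), as.integer(stride),
                      rng[1], rng[2], rng[3], rng[4])
  mi_from_hist(H)
}

#' Mutual information between two volumes
#'
#' Shannon mutual information (bits) of the joint intensity histogram of two
#' volumes on the same lattice.
#'
#' @param a,b [volume_grid] objects on the same lattice.
#' @param bins Number of histogram bins per image (>= 2), default 64.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(a, b, bins = 64L) {
  stopifnot_same_lattice(a, b)
  if (bins < 2) stop("`bins` must be >= 2")
  ra <- range(a$values); rb <- range(b$values)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant image: mutual information is 0")
    return(0)
  }
  d <- dim(a$values)
  mi_at(as.numeric(a$values), as.numeric(b$values), d,
        rigid_transform(), bins, 1L,
        c(ra[1], ra[2] + 1e-9, rb[1], rb[2] + 1e-9))
}

#' Rigid mutual-information registration
#'
#' Estimates the rigid transform aligning `moving` to `fixed` by maximizing
#' the mutual information of the joint intensity histogram: a deterministic
#' coarse grid search over integer translations followed by Nelder-Mead
#' refinement of all enabled parameters. The metric is evaluated on a
#' strided voxel subsample with trilinear interpolation.
#'
#' @param fixed,moving [volume_grid] objects on the same lattice. By
#'   convention the supra-edge (18.1 keV) volume is the fixed image.
#' @param max_shift_vox Half-width of the coarse translation search grid
#'   (voxels), default 5.
#' @param rotations Include the three rotation parameters in the refinement
#'   (default `TRUE`); `FALSE` gives translation-only registration.
#' @param bins Histogram bins for the metric, default 64.
#' @param stride Subsampling stride for the refinement metric; `NULL` picks
#'   one aiming at about 200,000 samples.
#' @param max_iter Nelder-Mead iteration cap.
#' @return A [rigid_transform] with attributes `mi` (metric at the optimum),
#'   `mi_identity`, and `trace` (data.frame of the coarse-search optimum and
#'   refinement metric values).
#' @export
register_volumes <- function(fixed, moving, max_shift_vox = 5L,
                             rotations = TRUE, bins = 64L, stride = NULL,
                             max_iter = 400L) {
  stopifnot_same_lattice(fixed, moving)
  d <- dim(fixed$values)
  fv <- as.numeric(fixed$values)
  mv <- as.numeric(moving$values)
  ra <- range(fv); rb <- range(mv)
  rng <- c(ra[1], ra[2] + 1e-9, rb[1], rb[2] + 1e-9)
  N <- prod(d)
  if (is.null(stride)) stride <- max(1L, ceiling((N / 2e5)^(1 / 3)))
  coarse_stride <- max(stride, ceiling((N / 3e4)^(1 / 3)))

  mi_id <- mi_at(fv, mv, d, rigid_transform(), bins, stride, rng)

  # coarse grid over integer translations
  shifts <- -max_shift_vox:max_shift_vox
  best <- list(mi = -Inf, t = c(0, 0, 0))
  for (s3 in shifts) for (s2 in shifts) for (s1 in shifts) {
    tr <- rigid_transform(c(s1, s2, s3))
    m <- mi_at(fv, mv, d, tr, bins, coarse_stride, rng)
    if (m > best$mi) best <- list(mi = m, t = c(s1, s2, s3))
  }

  npar <- if (rotations) 6L else 3L
  trace_mi <- numeric(0)
  objective <- function(par) {
    tr <- rigid_transform(par[1:3], if (rotations) par[4:6] else c(0, 0, 0))
    m <- mi_at(fv, mv, d, tr, bins, stride, rng)
    trace_mi[length(trace_mi) + 1L] <<- m
    -m
  }

  # deterministic coordinate-descent bracketing (translations in voxels,
  # rotations in degrees), halving the bracket each sweep; robust where a
  # simplex started at zero rotation stalls on the locally flat metric
  par <- c(best$t, rep(0, npar - 3L))
  fbest <- objective(par)
  h <- c(rep(1, 3), rep(1, npar - 3L))
  for (sweep in 1:4) {
    for (p in seq_len(npar)) {
      for (step in c(-1, -0.5, 0.5, 1) * h[p]) {
        cand <- par
        cand[p] <- cand[p] + step
        fc <- objective(cand)
        if (fc < fbest) { fbest <- fc; par <- cand }
      }
    }
    h <- h / 2
  }
  opt <- stats::optim(par, objective, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-9,
                                     parscale = rep(0.25, npar)))
  if (-opt$value < -fbest) opt$par <- par
  par <- opt$par
  refined <- rigid_transform(par[1:3], if (rotations) par[4:6] else c(0, 0, 0))
  mi_ref <- mi_at(fv, mv, d, refined, bins, stride, rng)
  if (mi_ref < best$mi) { # keep the grid optimum if refinement regressed
    refined <- rigid_transform(best$t)
    mi_ref <- mi_at(fv, mv, d, refined, bins, stride, rng)
  }
  attr(refined, "mi") <- mi_ref
  attr(refined, "mi_identity") <- mi_id
  attr(refined, "trace") <- data.frame(
    stage = c("identity", "coarse", rep("refine", length(trace_mi))),
    mi = c(mi_id, best$mi, trace_mi))
  refined
}
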