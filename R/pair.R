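#' Dual-energy volume pair
#'
#' Two co-acquired volumes of the same specimen bracketing the K-absorption
#' edge of the vascular contrast agent: `low` at 17.9 keV (sub-edge) and
#' `high` at 18.1 keV (supra-edge), plus the rigid transform aligning the
#' low-energy volume to the high-energy one (identity if already aligned,
#' `NULL` if unknown).
#'
#' @param low,high [volume_grid] objects on the same lattice.
#' @param transform Optional [rigid_transform] mapping `low` into alignment
#'   with `high`.
#' @return An object of class `dual_energy_pair`.
#' @export
dual_energy_pair <- function(low, high, transform = NULL) {
  stopifnot_same_lattice(low, high)
  if (!is.null(transform)) stopifnot(inherits(transform, "rigid_transform"))
  structure(list(low = low, high = high, transform = transform),
            class = "dual_energy_pair")
}

#' @export
print.dual_energy_pair <- function(x, ...) {
  d <- dim(x$low$values)
  cat(sprintf("<dual_energy_pair> %d x %d x %d voxels (%.3g um)\n",
              d[1], d[2], d[3], x$low$voxel_um))
  cat(sprintf("  transform: %s\n",
              if (is.null(x$transform)) "none" else "rigid (set)"))
  invisible(x)
}

#' Apply the stored (or a freshly estimated) alignment to a pair
#'
#' Resamples the low-energy volume onto the high-energy lattice using the
#' pair's transform, estimating one with [register_volumes()] (high fixed)
#' when none is stored.
#'
#' @param pair A [dual_energy_pair].
#' @param ... Passed on to [register_volumes()] when estimation is needed.
#' @return A [dual_energy_pair] with `low` resampled and `transform` set to
#'   the identity-applied record (attribute `applied_transform`).
#' @export
align_pair <- function(pair, ...) {
  stopifnot(inherits(pair, "dual_energy_pair"))
  tr <- pair$transform
  if (is.null(tr)) tr <- register_volumes(pair$high, pair$low, ...)
  low_aligned <- resample_volume(pair$low, tr)
  out <- dual_energy_pair(low_aligned, pair$high, rigid_transform())
  attr(out, "applied_transform") <- tr
  out
}
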