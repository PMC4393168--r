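#' 3D scalar volume with isotropic voxels
#'
#' The basic container of the package: a 3D numeric array plus the voxel
#' edge length in micrometers and an intensity-semantics tag. The first
#' array axis is the axial slice index (the drill-hole / region-of-interest
#' cylinder axis by default).
#'
#' @param values 3D numeric or logical array.
#' @param voxel_um Isotropic voxel edge length in micrometers.
#' @param semantics One of `"gray"` (8-bit gray levels, 0-255), `"mu"`
#'   (linear attenuation coefficient, /cm), `"dhap"` (hydroxyapatite-
#'   equivalent density, mg/cm^3) or `"binary"`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_um = 2.74,
                        semantics = c("gray", "mu", "dhap", "binary")) {
  semantics <- match.arg(semantics)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("`voxel_um` must be a single positive number")
  if (semantics == "gray") {
    rng <- range(values)
    if (rng[1] < 0 || rng[2] > 255)
      stop("gray volumes must lie in [0, 255]")
  }
  if (semantics == "binary") values <- array(as.logical(values), dim(values))
  structure(list(values = values, voxel_um = voxel_um, semantics = semantics),
            class = "volume_grid")
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels (%.3g um), semantics: %s\n",
              d[1], d[2], d[3], x$voxel_um, x$semantics))
  if (x$semantics == "binary") {
    cat(sprintf("  foreground: %d voxels\n", sum(x$values)))
  } else {
    cat(sprintf("  range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

stopifnot_same_lattice <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("volumes are on different lattices: ",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"))
  if (!isTRUE(all.equal(a$voxel_um, b$voxel_um)))
    stop("volumes have different voxel sizes")
  invisible(TRUE)
}

#' Read a multi-page 8-bit grayscale TIFF stack
#'
#' Pages are axial slices in order; the page index becomes the first array
#' axis. Only 8-bit single-channel stacks with a constant page shape are
#' accepted.
#'
#' @param path Path to a multi-page TIFF file.
#' @param voxel_um Voxel size to attach (not stored in the TIFF tags).
#' @param semantics Intensity semantics tag, default `"gray"`.
#' @return A [volume_grid].
#' @export
read_stack <- function(path, voxel_um = 2.74, semantics = "gray") {
  if (!file.exists(path))
    stop("stack not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L)
    stop("no pages in TIFF stack: ", path)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("pages differ in shape in ", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE)))
    stop("unsupported format (multi-channel pages) in ", path)
  mx <- max(vapply(pages, max, 0))
  if (mx > 255)
    stop("unsupported format: expected 8-bit data, found values > 255 in ", path)
  d2 <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d2))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  volume_grid(arr, voxel_um = voxel_um, semantics = semantics)
}

#' Write a volume as a multi-page 8-bit grayscale TIFF stack
#'
#' Gray volumes are rounded and clipped to 0-255; binary volumes are written
#' as 0/255. The round trip `read_stack(write_stack(x))` is lossless for
#' integer gray data.
#'
#' @param vol A [volume_grid] with `gray` or `binary` semantics.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  v <- vol$values
  if (vol$semantics == "binary") v <- array(ifelse(v, 255, 0), dim(v))
  v <- pmin(pmax(round(v), 0), 255)
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Cylindrical region-of-interest specification
#'
#' The analysis cylinder inside the cortical defect: by default 720 um in
#' diameter and 300 um high, with its axis along the first array axis (the
#' drill-hole direction).
#'
#' @param center Cylinder center in voxel coordinates (axis-1, axis-2,
#'   axis-3; 1-based, may be fractional). `NULL` centers it in the lattice.
#' @param diameter_um Cylinder diameter in micrometers.
#' @param height_um Cylinder height in micrometers.
#' @param axis Cylinder axis (1, 2 or 3); default 1.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center = NULL, diameter_um = 720, height_um = 300, axis = 1L) {
  stopifnot(diameter_um >= 0, height_um >= 0, axis %in% 1:3)
  structure(list(center = center, diameter_um = diameter_um,
                 height_um = height_um, axis = as.integer(axis)),
            class = "roi_spec")
}

#' Rasterize a cylindrical ROI on a volume lattice
#'
#' A voxel belongs to the ROI when its center lies inside the cylinder.
#' The mask carries the ROI volume (voxel count times voxel volume) in mm^3
#' as attribute `roi_volume_mm3`.
#'
#' @param roi An [roi_spec].
#' @param grid A [volume_grid] defining the lattice.
#' @return A binary [volume_grid]; attribute `roi_volume_mm3` holds the
#'   ROI volume in mm^3.
#' @export
roi_mask <- function(roi, grid) {
  stopifnot(inherits(roi, "roi_spec"), inherits(grid, "volume_grid"))
  d <- dim(grid$values)
  vx <- grid$voxel_um
  ctr <- roi$center
  if (is.null(ctr)) ctr <- (d + 1) / 2
  r_vox <- roi$diameter_um / 2 / vx
  h_vox <- roi$height_um / vx
  ax <- roi$axis
  perp <- setdiff(1:3, ax)
  # containment check
  if (ctr[ax] - h_vox / 2 < 0.5 - 1e-9 || ctr[ax] + h_vox / 2 > d[ax] + 0.5 + 1e-9 ||
      any(ctr[perp] - r_vox < 0.5 - 1e-9) || any(ctr[perp] + r_vox > d[perp] + 0.5 + 1e-9))
    stop("ROI cylinder exceeds the lattice")
  co <- lapply(1:3, function(a) seq_len(d[a]) - ctr[a])
  in_ax <- abs(co[[ax]]) <= h_vox / 2
  rr <- outer(co[[perp[1]]]^2, co[[perp[2]]]^2, `+`)
  in_rad <- rr <= r_vox^2
  mask <- array(FALSE, d)
  # broadcast along the cylinder axis
  if (ax == 1L) {
    for (i in which(in_ax)) mask[i, , ] <- in_rad
  } else if (ax == 2L) {
    for (i in which(in_ax)) mask[, i, ] <- in_rad
  } else {
    for (i in which(in_ax)) mask[, , i] <- in_rad
  }
  out <- volume_grid(mask, voxel_um = vx, semantics = "binary")
  attr(out, "roi_volume_mm3") <- sum(mask) * (vx * 1e-3)^3
  out
}

#' ROI volume in cubic millimeters
#'
#' @param mask A binary [volume_grid], typically from [roi_mask()].
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
roi_volume_mm3 <- function(mask) {
  v <- attr(mask, "roi_volume_mm3")
  if (!is.null(v)) return(v)
  sum(mask$values) * (mask$voxel_um * 1e-3)^3
}
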