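#' Attenuation-to-mineral-density calibration line
#'
#' Holds the constants linking 8-bit gray levels, the linear attenuation
#' coefficient mu (/cm) at 17.9 keV, and hydroxyapatite-equivalent density
#' d.HAp (mg/cm^3): `d.HAp = slope * mu + intercept`, with the bone
#' classification threshold expressed in both domains. The defaults encode
#' the published calibration (slope 136, intercept -142); the bone threshold
#' mu >= 4.74 /cm corresponds to d.HAp of about 500 mg/cm^3, and the
#' constructor enforces that self-consistency to within 5 mg/cm^3.
#'
#' The gray-to-mu scaling is acquisition-dependent and therefore a plain
#' configuration parameter. The default, 0.392 /cm per gray level, is the
#' scaling applied to the reconstructed stacks before subtraction; an
#' alternative scaling of 7.97/136 ~= 0.0586 reproduces a gray-domain
#' density line `d.HAp = 7.97 * gray - 142` and can be set when working with
#' stacks normalized that way.
#'
#' @param slope_mu_to_dhap Slope of the mu -> d.HAp line, (mg/cm^3)/(/cm).
#' @param intercept_dhap Intercept of the line, mg/cm^3.
#' @param gray_to_mu_factor Gray level -> mu scaling, (/cm) per gray level.
#' @param bone_mu_threshold Bone classification threshold in mu, /cm.
#' @param bone_dhap_threshold The same threshold in d.HAp, mg/cm^3.
#' @return An object of class `calibration_line`.
#' @export
calibration_line <- function(slope_mu_to_dhap = 136,
                             intercept_dhap = -142,
                             gray_to_mu_factor = 0.392,
                             bone_mu_threshold = 4.74,
                             bone_dhap_threshold = 500) {
  if (slope_mu_to_dhap <= 0) stop("`slope_mu_to_dhap` must be positive")
  if (gray_to_mu_factor <= 0) stop("`gray_to_mu_factor` must be positive")
  mismatch <- abs(slope_mu_to_dhap * bone_mu_threshold + intercept_dhap -
                    bone_dhap_threshold)
  if (mismatch > 5)
    stop(sprintf(paste0("inconsistent calibration constants: slope * threshold + ",
                        "intercept = %.2f, but bone_dhap_threshold = %.2f"),
                 slope_mu_to_dhap * bone_mu_threshold + intercept_dhap,
                 bone_dhap_threshold))
  structure(list(slope_mu_to_dhap = slope_mu_to_dhap,
                 intercept_dhap = intercept_dhap,
                 gray_to_mu_factor = gray_to_mu_factor,
                 bone_mu_threshold = bone_mu_threshold,
                 bone_dhap_threshold = bone_dhap_threshold),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> d.HAp = %g * mu %+g; mu = %g * gray\n",
              x$slope_mu_to_dhap, x$intercept_dhap, x$gray_to_mu_factor))
  cat(sprintf("  bone threshold: mu >= %g /cm (d.HAp >= %g mg/cm^3)\n",
              x$bone_mu_threshold, x$bone_dhap_threshold))
  invisible(x)
}

#' Convert gray levels to linear attenuation
#'
#' @param gray Gray levels in `[0, 255]` (vector, array or [volume_grid]).
#' @param cal A [calibration_line].
#' @return mu in /cm, same shape as the input (a [volume_grid] in, a
#'   [volume_grid] with `mu` semantics out).
#' @export
gray_to_mu <- function(gray, cal = calibration_line()) {
  if (inherits(gray, "volume_grid")) {
    out <- gray
    out$values <- gray_to_mu(gray$values, cal)
    out$semantics <- "mu"
    return(out)
  }
  if (any(gray < 0)) stop("negative gray values")
  cal$gray_to_mu_factor * gray
}

#' Convert linear attenuation to gray levels
#'
#' Inverse of [gray_to_mu()]; values are not rounded or clipped.
#' @inheritParams gray_to_mu
#' @param mu Attenuation in /cm.
#' @return Gray levels.
#' @export
mu_to_gray <- function(mu, cal = calibration_line()) {
  mu / cal$gray_to_mu_factor
}

#' Convert linear attenuation to hydroxyapatite density
#'
#' Affine map `d.HAp = slope * mu + intercept`. Negative outputs are
#' permitted and read as sub-mineralization-threshold material.
#'
#' @param mu Attenuation in /cm (vector, array or [volume_grid]).
#' @param cal A [calibration_line].
#' @return d.HAp in mg/cm^3.
#' @export
mu_to_dhap <- function(mu, cal = calibration_line()) {
  if (inherits(mu, "volume_grid")) {
    out <- mu
    out$values <- mu_to_dhap(mu$values, cal)
    out$semantics <- "dhap"
    return(out)
  }
  cal$slope_mu_to_dhap * mu + cal$intercept_dhap
}

#' Convert hydroxyapatite density to linear attenuation
#'
#' Inverse of [mu_to_dhap()]: `mu = (d.HAp - intercept) / slope`.
#' @param dhap d.HAp in mg/cm^3.
#' @param cal A [calibration_line].
#' @return mu in /cm.
#' @export
dhap_to_mu <- function(dhap, cal = calibration_line()) {
  (dhap - cal$intercept_dhap) / cal$slope_mu_to_dhap
}
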