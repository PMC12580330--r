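#' Spectrometer field settings
#'
#' Bundles the static-field parameters needed to convert between the ppm
#' offset axis and angular frequency offsets: the proton Larmor frequency and
#' the position of the water resonance on the standard ppm axis (TMS at 0).
#'
#' @param larmor_frequency_MHz Proton spectrometer frequency in MHz.
#' @param water_reference_ppm Chemical shift of the water resonance (ppm).
#' @return An object of class `mt_field`.
#' @examples
#' fs <- field_settings()        # 700 MHz, water at 4.7 ppm
#' @export
field_settings <- function(larmor_frequency_MHz = 700,
                           water_reference_ppm = 4.7) {
  check_finite(larmor_frequency_MHz, "larmor_frequency_MHz")
  check_finite(water_reference_ppm, "water_reference_ppm")
  if (length(larmor_frequency_MHz) != 1L || larmor_frequency_MHz <= 0) {
    cmt_stop("invalid_argument", "larmor_frequency_MHz must be a single positive number")
  }
  structure(
    list(larmor_frequency_MHz = larmor_frequency_MHz,
         water_reference_ppm = water_reference_ppm),
    class = "mt_field"
  )
}

#' Convert a ppm offset to an angular frequency offset
#'
#' At a Larmor frequency of `f` MHz, 1 ppm corresponds to `f` Hz, so the
#' angular offset is `2 * pi * (offset_ppm - center_ppm) * f` rad/s. The sign
#' is preserved: upfield offsets (lower ppm than the center) come out
#' negative.
#'
#' @param offset_ppm Saturation offset(s) on the ppm axis.
#' @param center_ppm Reference position (e.g. a pool center) on the ppm axis.
#' @param field A [field_settings()] object.
#' @return Angular frequency offset(s) in rad/s.
#' @seealso [angular_offset_to_ppm()] for the inverse.
#' @examples
#' fs <- field_settings(700, 4.7)
#' ppm_to_angular_offset(5.7, 4.7, fs)  # 2*pi*700 ~ 4398 rad/s
#' @export
ppm_to_angular_offset <- function(offset_ppm, center_ppm, field) {
  stopifnot(inherits(field, "mt_field"))
  check_finite(offset_ppm, "offset_ppm")
  check_finite(center_ppm, "center_ppm")
  2 * pi * (offset_ppm - center_ppm) * field$larmor_frequency_MHz
}

#' @rdname ppm_to_angular_offset
#' @param delta_omega Angular frequency offset(s) in rad/s.
#' @export
angular_offset_to_ppm <- function(delta_omega, center_ppm, field) {
  stopifnot(inherits(field, "mt_field"))
  check_finite(delta_omega, "delta_omega")
  check_finite(center_ppm, "center_ppm")
  delta_omega / (2 * pi * field$larmor_frequency_MHz) + center_ppm
}
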