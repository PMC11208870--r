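#' OCT acquisition configuration
#'
#' Bundles the optical parameters of a phase-sensitive OCT acquisition:
#' central wavelength, axial sampling unit (the physical depth spanned by
#' one pixel, in air), lateral pixel pitch, frame rate and the per-depth
#' refractive-index profile used to convert optical phase into physical
#' displacement.
#'
#' @param wavelength_nm Central wavelength of the swept/broadband source
#'   in nanometres. Default 1200.
#' @param asu_um Axial sampling unit in micrometres, measured in air; the
#'   in-tissue pixel depth is `asu_um / n(z)`. Default 9.5.
#' @param lateral_sampling_um Lateral pixel pitch in micrometres.
#'   Default 35.
#' @param frame_rate_hz B-scan repetition rate in Hz. Default 33.
#' @param n_frames Number of B-scans per acquisition. Default 256.
#' @param n_z,n_x Frame dimensions in pixels (depth x lateral).
#' @param refractive_index_profile Numeric vector of length `n_z` giving
#'   n(z) per depth pixel, or a single value recycled over depth.
#'   Default homogeneous 1.49 (crystalline lens).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(wavelength_nm = 1200, asu_um = 9.5,
                          lateral_sampling_um = 35, frame_rate_hz = 33,
                          n_frames = 256, n_z = 256L, n_x = 16L,
                          refractive_index_profile = 1.49) {
  stopifnot(wavelength_nm > 0, asu_um > 0, lateral_sampling_um > 0,
            frame_rate_hz > 0, n_frames >= 2, n_z >= 2, n_x >= 1)
  n_of_z <- rep_len(as.numeric(refractive_index_profile), n_z)
  if (any(!is.finite(n_of_z)) || any(n_of_z < 1))
    stop("refractive_index_profile must be finite and >= 1 everywhere")
  structure(list(
    wavelength_nm = as.numeric(wavelength_nm),
    asu_um = as.numeric(asu_um),
    lateral_sampling_um = as.numeric(lateral_sampling_um),
    frame_rate_hz = as.numeric(frame_rate_hz),
    n_frames = as.integer(n_frames),
    n_z = as.integer(n_z),
    n_x = as.integer(n_x),
    n_of_z = n_of_z
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "OCT configuration: %g nm, asu %g um (air), %g Hz, %d frames of %d x %d px, n(z) %s\n",
    x$wavelength_nm, x$asu_um, x$frame_rate_hz, x$n_frames, x$n_z, x$n_x,
    if (length(unique(x$n_of_z)) == 1L) sprintf("= %.3f", x$n_of_z[1])
    else sprintf("in [%.3f, %.3f]", min(x$n_of_z), max(x$n_of_z))))
  invisible(x)
}

#' Maximum unambiguous interframe displacement
#'
#' The phase-sensitive estimator is valid while the interframe phase stays
#' below pi in magnitude, i.e. while the interframe axial displacement is
#' below `wavelength / (4 n)`.
#'
#' @param optics An [optics_config()].
#' @return Displacement bound in nanometres (per depth pixel; vector over z).
#' @export
phase_wrap_limit_nm <- function(optics) {
  optics$wavelength_nm / (4 * optics$n_of_z)
}
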