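#' Combine light sources expressed in log10 Trolands
#'
#' Background fields in adaptive-optics stimulation rigs are typically the sum
#' of several sources (wavefront-sensing beam, imaging raster, stimulus-channel
#' leak, external projector), each calibrated in log10 photopic Trolands.
#' Retinal illuminances add linearly, so the combined level is the log10 of the
#' sum of the linear Troland values.
#'
#' @param log_troland Numeric vector of source levels, log10 Trolands.
#' @return Combined level in log10 Trolands (scalar).
#' @examples
#' combine_sources(c(2.02, 1.99, 2.52)) # ~2.73
#' @export
combine_sources <- function(log_troland) {
  if (length(log_troland) == 0L) {
    stop("`log_troland` must contain at least one source")
  }
  if (!is.numeric(log_troland) || any(!is.finite(log_troland))) {
    stop("`log_troland` must be finite numeric")
  }
  log10(sum(10^log_troland))
}

#' Linear luminance ratio between two light levels
#'
#' @param log_a,log_b Levels in log10 Trolands.
#' @return `10^(log_a - log_b)`, the linear ratio a:b.
#' @examples
#' luminance_ratio(5.19, 2.73) # ~288, "about 290 times"
#' @export
luminance_ratio <- function(log_a, log_b) {
  stopifnot(is.finite(log_a), is.finite(log_b))
  10^(log_a - log_b)
}

#' Angular sampling resolution of a square raster
#'
#' @param field_deg Field size of the raster in degrees (side of the square).
#' @param pixels Number of pixels per raster side.
#' @return Arcminutes per pixel.
#' @examples
#' sampling_resolution(0.95, 512) # ~0.111 arcmin/px
#' @export
sampling_resolution <- function(field_deg, pixels) {
  if (!is.numeric(field_deg) || field_deg <= 0 ||
      !is.numeric(pixels) || pixels <= 0) {
    stop("`field_deg` and `pixels` must be positive")
  }
  field_deg * 60 / pixels
}

#' Convert a corneal photon count to retinal illuminance (optional helper)
#'
#' Retinal illuminance in Trolands for a monochromatic flash delivered in
#' Maxwellian view, from first principles: the photon count is converted to
#' radiant energy at `wavelength_nm`, to luminous energy through the photopic
#' luminous-efficiency value supplied by the caller, and then to Trolands via
#' the stimulus duration and angular area. All conversion constants are
#' explicit arguments because reported values depend on the calibration chain
#' of the individual instrument; no pipeline stage calls this function.
#'
#' @param photons Photons at the cornea per flash.
#' @param wavelength_nm Wavelength in nanometres.
#' @param duration_s Flash duration in seconds.
#' @param area_deg2 Stimulus angular area in square degrees.
#' @param luminous_efficacy Photopic luminous efficacy at `wavelength_nm`
#'   in lm/W (683 x V(lambda)).
#' @return Retinal illuminance in log10 Trolands.
#' @export
photons_to_log_troland <- function(photons, wavelength_nm, duration_s,
                                   area_deg2, luminous_efficacy) {
  stopifnot(photons > 0, wavelength_nm > 0, duration_s > 0,
            area_deg2 > 0, luminous_efficacy > 0)
  h <- 6.62607015e-34 # J s
  c <- 299792458      # m/s
  energy_j <- photons * h * c / (wavelength_nm * 1e-9)
  flux_lm <- energy_j * luminous_efficacy / duration_s
  # Troland = luminance (cd/m^2) x pupil area (mm^2). In Maxwellian view the
  # equivalent luminance is flux / (solid angle x pupil area), so the pupil
  # area cancels and Td = 1e6 x flux / solid angle. 1 deg^2 = (pi/180)^2 sr.
  solid_angle_sr <- area_deg2 * (pi / 180)^2
  log10(1e6 * flux_lm / solid_angle_sr)
}
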