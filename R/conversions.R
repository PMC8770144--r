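# Photon energy / wavelength / Bragg-angle conversions.
# hc = 12.39842 keV * Angstrom.

HC_KEV_ANGSTROM <- 12.39842

#' Photon energy to wavelength
#' @param energy_kev Photon energy in keV (> 0).
#' @return Wavelength in Angstrom.
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (any(energy_kev <= 0)) stop("photon energy must be positive")
  HC_KEV_ANGSTROM / energy_kev
}

#' Wavelength to photon energy
#' @param wavelength Wavelength in Angstrom (> 0).
#' @return Photon energy in keV.
#' @export
wavelength_to_energy <- function(wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  HC_KEV_ANGSTROM / wavelength
}

#' d spacing to scattering angle 2-theta
#'
#' Bragg's law, lambda = 2 d sin(theta). A reflection with lambda/(2d) > 1
#' lies outside the Ewald sphere and is unreachable at that wavelength.
#'
#' @param d d spacing in Angstrom.
#' @param wavelength Wavelength in Angstrom.
#' @return 2-theta in degrees.
#' @export
d_to_two_theta <- function(d, wavelength) {
  s <- wavelength / (2 * d)
  if (any(s > 1)) stop("reflection outside the Ewald sphere: lambda/(2d) > 1")
  2 * rad2deg(asin(s))
}

#' Scattering angle 2-theta to d spacing
#' @param two_theta 2-theta in degrees, in (0, 180].
#' @param wavelength Wavelength in Angstrom.
#' @return d spacing in Angstrom.
#' @export
two_theta_to_d <- function(two_theta, wavelength) {
  if (any(two_theta <= 0) || any(two_theta > 180)) stop("two_theta must be in (0, 180]")
  wavelength / (2 * sin(deg2rad(two_theta / 2)))
}
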