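#' Physical constants (CODATA 2018)
#'
#' Fixed CODATA-2018 recommended values used by every formula in the package.
#' Hard-coded (not configurable) so that results are reproducible bit-for-bit
#' across installations.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{elementary_charge}{e, C}
#'   \item{vacuum_permittivity}{epsilon_0, F/m}
#'   \item{electron_mass}{m_e, kg}
#'   \item{speed_of_light}{c, m/s}
#'   \item{planck_constant}{h, J s}
#'   \item{ev_nm_product}{hc expressed in eV nm (1239.84198)}
#' }
#' @export
physical_constants <- list(
  elementary_charge   = 1.602176634e-19,
  vacuum_permittivity = 8.8541878128e-12,
  electron_mass       = 9.1093837015e-31,
  speed_of_light      = 299792458,
  planck_constant     = 6.62607015e-34,
  ev_nm_product       = 1239.84198
)

.check_wavelength <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) == 0 ||
      anyNA(wavelength_nm) || any(wavelength_nm <= 0)) {
    stop("wavelength must be a positive number (nm)", call. = FALSE)
  }
  invisible(wavelength_nm)
}

#' Convert wavelength to photon energy
#'
#' @param wavelength_nm Wavelength in nm (positive; vectorized).
#' @return Photon energy in eV (hc / lambda).
#' @examples
#' nm_to_ev(1239.84198)  # 1 eV
#' nm_to_ev(458.2)       # vertical emission energy of a blue emitter
#' @export
nm_to_ev <- function(wavelength_nm) {
  .check_wavelength(wavelength_nm)
  physical_constants$ev_nm_product / wavelength_nm
}

#' Convert wavelength to wavenumber in inverse micrometers
#'
#' This is the energy-gap argument of the empirical internal-conversion
#' formula: an emission wavelength of 500 nm corresponds to 2.0 um^-1.
#'
#' @inheritParams nm_to_ev
#' @return Wavenumber in um^-1 (1000 / lambda_nm).
#' @export
nm_to_inverse_micrometers <- function(wavelength_nm) {
  .check_wavelength(wavelength_nm)
  1000 / wavelength_nm
}

#' Convert wavelength to angular frequency
#'
#' @inheritParams nm_to_ev
#' @return Angular frequency omega = 2 pi c / lambda in rad/s.
#' @export
nm_to_angular_frequency <- function(wavelength_nm) {
  .check_wavelength(wavelength_nm)
  2 * pi * physical_constants$speed_of_light / (wavelength_nm * 1e-9)
}
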