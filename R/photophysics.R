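#' Radiative rate constant from Einstein's spontaneous emission formula
#'
#' Computes the spontaneous-emission (fluorescence) rate constant
#' \deqn{k_r = \frac{f_{21}\,\omega_{21}^2\,e^2}{2\pi\,\epsilon_0\,m\,c^3}
#'   \cdot \frac{1}{\mathrm{solvent\_factor}}}
#' where \eqn{f_{21}} is the emission oscillator strength and
#' \eqn{\omega_{21} = 2\pi c/\lambda} the angular emission frequency.
#'
#' The optional `solvent_factor` is an explicit divisor applied to the
#' vacuum formula. With the default 1.0 the formula is used as written;
#' dividing by ~1.333 (the refractive index of water) is the documented
#' preset that reproduces published rate constants computed for aqueous
#' solution. The vacuum form agrees with the standard closed-form
#' restatement of the Einstein A coefficient,
#' \eqn{k_r \approx 6.6703\times 10^{15}\, f/\lambda[\mathrm{\AA}]^2},
#' to better than 0.1%.
#'
#' @param oscillator_strength Emission oscillator strength (dimensionless,
#'   non-negative).
#' @param emission_wavelength_nm Vertical emission wavelength in nm.
#' @param solvent_factor Positive dimensionless divisor (default 1.0).
#' @return Radiative rate constant in s^-1.
#' @examples
#' radiative_rate(1.2263, 458.2, solvent_factor = 1.333)  # about 2.92e8 s^-1
#' @export
radiative_rate <- function(oscillator_strength, emission_wavelength_nm,
                           solvent_factor = 1.0) {
  if (!is.numeric(oscillator_strength) || anyNA(oscillator_strength) ||
      any(oscillator_strength < 0)) {
    stop("oscillator_strength must be non-negative", call. = FALSE)
  }
  .check_wavelength(emission_wavelength_nm)
  if (!is.numeric(solvent_factor) || anyNA(solvent_factor) ||
      any(solvent_factor <= 0)) {
    stop("solvent_factor must be positive", call. = FALSE)
  }
  k <- physical_constants
  omega <- nm_to_angular_frequency(emission_wavelength_nm)
  num <- oscillator_strength * omega^2 * k$elementary_charge^2
  den <- 2 * pi * k$vacuum_permittivity * k$electron_mass *
    k$speed_of_light^3 * solvent_factor
  num / den
}

#' Internal-conversion rate constant from the energy-gap empirical law
#'
#' Estimates the non-radiative S1 -> S0 internal-conversion rate with the
#' widely used empirical relation
#' \deqn{k_{ic} \approx 10^{\,12 - 2\,\tilde\nu}\ \mathrm{s}^{-1}}
#' where \eqn{\tilde\nu} is the vertical emission energy expressed as a
#' wavenumber in inverse micrometers (\eqn{1000/\lambda_{nm}}). The rate
#' grows as the emission gap shrinks (red emitters convert faster), the
#' energy-gap-law direction.
#'
#' @param emission_wavelength_nm Vertical emission wavelength in nm.
#' @return Internal-conversion rate constant in s^-1.
#' @examples
#' internal_conversion_rate(500)    # exactly 1e8 s^-1
#' internal_conversion_rate(458.2)  # about 4.32e7 s^-1
#' @export
internal_conversion_rate <- function(emission_wavelength_nm) {
  .check_wavelength(emission_wavelength_nm)
  10^(12 - 2 * nm_to_inverse_micrometers(emission_wavelength_nm))
}

#' Fluorescence quantum yield from rate constants
#'
#' With intersystem crossing neglected the non-radiative decay is dominated
#' by internal conversion, and
#' \deqn{\varphi = \frac{k_r}{k_r + k_{ic}}.}
#'
#' @param radiative_rate Radiative rate constant k_r in s^-1 (>= 0).
#' @param internal_conversion_rate Internal-conversion rate constant k_ic in
#'   s^-1 (> 0).
#' @return Quantum yield in `[0, 1)`.
#' @examples
#' quantum_yield(2.94e8, 4.31e7)  # about 0.872
#' @export
quantum_yield <- function(radiative_rate, internal_conversion_rate) {
  if (!is.numeric(radiative_rate) || anyNA(radiative_rate) ||
      any(radiative_rate < 0)) {
    stop("radiative_rate must be non-negative", call. = FALSE)
  }
  if (!is.numeric(internal_conversion_rate) ||
      anyNA(internal_conversion_rate) || any(internal_conversion_rate <= 0)) {
    stop("internal_conversion_rate must be positive", call. = FALSE)
  }
  radiative_rate / (radiative_rate + internal_conversion_rate)
}

#' Quantum-yield-corrected spectral intensity
#'
#' Scales a band intensity from species A to species B so that calculated
#' spectra become comparable with measured ones:
#' \deqn{I_B = I_A \cdot \frac{\varphi_B}{\varphi_A}
#'   \cdot \frac{\lambda_A}{\lambda_B}.}
#'
#' @param intensity_a Intensity of the reference band (arbitrary units, > 0).
#' @param phi_a,phi_b Quantum yields of A and B (> 0).
#' @param wavelength_a_nm,wavelength_b_nm Emission wavelengths in nm (> 0).
#' @return The corrected intensity I_B in the units of `intensity_a`.
#' @examples
#' intensity_scale(1, 0.870, 0.644, 458.2, 512.9)  # about 0.661
#' @export
intensity_scale <- function(intensity_a, phi_a, phi_b,
                            wavelength_a_nm, wavelength_b_nm) {
  args <- c(intensity_a, phi_a, phi_b, wavelength_a_nm, wavelength_b_nm)
  if (!is.numeric(args) || anyNA(args) || any(args <= 0)) {
    stop("all arguments to intensity_scale must be positive", call. = FALSE)
  }
  intensity_a * (phi_b / phi_a) * (wavelength_a_nm / wavelength_b_nm)
}

#' Mean absolute relative excitation-energy deviation
#'
#' Compares calculated and experimental emission wavelengths on the energy
#' scale. Since E is proportional to 1/lambda, the relative energy deviation
#' of a pair is `|lambda_exp / lambda_calc - 1|`; the unweighted mean over
#' pairs is returned as a percentage.
#'
#' @param calculated_nm Calculated wavelengths in nm.
#' @param experimental_nm Experimental wavelengths in nm (same length).
#' @return Mean absolute relative energy deviation in percent.
#' @examples
#' mean_energy_deviation(c(458.2, 512.9), c(454.0, 514.0))  # about 0.57
#' @export
mean_energy_deviation <- function(calculated_nm, experimental_nm) {
  if (length(calculated_nm) == 0 ||
      length(calculated_nm) != length(experimental_nm)) {
    stop("need equal-length, non-empty wavelength vectors", call. = FALSE)
  }
  .check_wavelength(calculated_nm)
  .check_wavelength(experimental_nm)
  100 * mean(abs(experimental_nm / calculated_nm - 1))
}

#' Assemble the photophysics of one emission transition
#'
#' Composes the radiative rate, internal-conversion rate and quantum yield
#' for a single emissive transition row.
#'
#' @param transition One row of a [transition_table()] with
#'   `kind == "emission"` and a non-missing oscillator strength.
#' @param solvent_factor Divisor applied to the radiative rate (see
#'   [radiative_rate()]).
#' @return A `rate_result` list with fields `molecule_id`,
#'   `emission_wavelength_nm`, `oscillator_strength`, `solvent_factor`,
#'   `radiative_rate`, `internal_conversion_rate` and `quantum_yield`.
#' @export
assemble_photophysics <- function(transition, solvent_factor = 1.0) {
  if (!is.data.frame(transition) || nrow(transition) != 1) {
    stop("transition must be a single table row", call. = FALSE)
  }
  if (!identical(transition$kind, "emission")) {
    stop("photophysics requires a calculated emission transition, got kind '",
         transition$kind, "'", call. = FALSE)
  }
  if (is.na(transition$oscillator_strength)) {
    stop("transition has no oscillator strength", call. = FALSE)
  }
  kr <- radiative_rate(transition$oscillator_strength,
                       transition$wavelength_nm, solvent_factor)
  kic <- internal_conversion_rate(transition$wavelength_nm)
  res <- list(
    molecule_id = transition$molecule_id,
    emission_wavelength_nm = transition$wavelength_nm,
    oscillator_strength = transition$oscillator_strength,
    solvent_factor = solvent_factor,
    radiative_rate = kr,
    internal_conversion_rate = kic,
    quantum_yield = quantum_yield(kr, kic)
  )
  class(res) <- "rate_result"
  res
}

#' Photophysics for every emission row of a transition table
#'
#' @param tab A [transition_table()].
#' @param solvent_factor Divisor applied to the radiative rate.
#' @return A data frame with one row per calculated emission transition that
#'   carries an oscillator strength: columns `molecule_id`, `method`,
#'   `emission_wavelength_nm`, `oscillator_strength`, `k_r`, `k_ic`, `phi`.
#' @export
rate_table <- function(tab, solvent_factor = 1.0) {
  tab <- validate_transition_table(tab)
  keep <- tab$kind == "emission" & !is.na(tab$oscillator_strength)
  em <- tab[keep, , drop = FALSE]
  if (nrow(em) == 0) {
    return(data.frame(molecule_id = character(), method = character(),
                      emission_wavelength_nm = numeric(),
                      oscillator_strength = numeric(),
                      k_r = numeric(), k_ic = numeric(), phi = numeric(),
                      stringsAsFactors = FALSE))
  }
  kr <- radiative_rate(em$oscillator_strength, em$wavelength_nm,
                       solvent_factor)
  kic <- internal_conversion_rate(em$wavelength_nm)
  data.frame(
    molecule_id = em$molecule_id,
    method = em$method,
    emission_wavelength_nm = em$wavelength_nm,
    oscillator_strength = em$oscillator_strength,
    k_r = kr,
    k_ic = kic,
    phi = quantum_yield(kr, kic),
    stringsAsFactors = FALSE
  )
}

#' Pair calculated and experimental emission rows and report the deviation
#'
#' Matches each molecule's calculated emission wavelength with its
#' experimental counterpart (kind `emission_experimental`) and computes the
#' mean absolute relative excitation-energy deviation.
#'
#' @param tab A [transition_table()] containing both calculated and
#'   experimental emission rows.
#' @return A list with `pairs` (data frame of molecule, calculated and
#'   experimental wavelengths) and `mean_deviation_percent`.
#' @export
deviation_report <- function(tab) {
  tab <- validate_transition_table(tab)
  calc <- tab[tab$kind == "emission", , drop = FALSE]
  expt <- tab[tab$kind == "emission_experimental", , drop = FALSE]
  idx <- match(paste(calc$molecule_id, calc$state_from, calc$state_to),
               paste(expt$molecule_id, expt$state_from, expt$state_to))
  ok <- !is.na(idx)
  if (!any(ok)) {
    stop("no calculated/experimental emission pairs found", call. = FALSE)
  }
  pairs <- data.frame(
    molecule_id = calc$molecule_id[ok],
    calculated_nm = calc$wavelength_nm[ok],
    experimental_nm = expt$wavelength_nm[idx[ok]],
    stringsAsFactors = FALSE
  )
  list(pairs = pairs,
       mean_deviation_percent = mean_energy_deviation(pairs$calculated_nm,
                                                      pairs$experimental_nm))
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "%s: lambda_em = %.1f nm, f = %.4f\n  k_r = %.3e s^-1  k_ic = %.3e s^-1  phi = %.3f\n",
    x$molecule_id, x$emission_wavelength_nm, x$oscillator_strength,
    x$radiative_rate, x$internal_conversion_rate, x$quantum_yield))
  invisible(x)
}
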