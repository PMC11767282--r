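#' Construct a stick spectrum
#'
#' A stick spectrum is the raw output of an excited-state calculation: a set
#' of (wavelength, oscillator strength) lines awaiting lineshape convolution.
#'
#' @param wavelength_nm Positive stick wavelengths in nm.
#' @param weight Non-negative stick weights (oscillator strengths).
#' @return A `stick_spectrum` data frame.
#' @export
stick_spectrum <- function(wavelength_nm, weight) {
  if (length(wavelength_nm) != length(weight)) {
    stop("wavelength and weight must have equal length", call. = FALSE)
  }
  .check_wavelength(wavelength_nm)
  if (anyNA(weight) || any(weight < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  out <- data.frame(wavelength_nm = wavelength_nm, weight = weight)
  class(out) <- c("stick_spectrum", "data.frame")
  out
}

#' Default wavelength grid for broadening
#'
#' 1 nm spacing spanning from 100 nm below the bluest stick to 100 nm above
#' the reddest, clipped at 1 nm.
#'
#' @param sticks A [stick_spectrum()].
#' @return Numeric vector of grid wavelengths in nm.
#' @export
default_grid <- function(sticks) {
  lo <- max(1, floor(min(sticks$wavelength_nm)) - 100)
  hi <- ceiling(max(sticks$wavelength_nm)) + 100
  seq(lo, hi, by = 1)
}

#' Gaussian-broaden a stick spectrum
#'
#' Each stick contributes a Gaussian in energy space centred at its
#' transition energy with area proportional to its weight; contributions
#' sum. The broadened curve is evaluated at the energies of the supplied
#' wavelength grid points, so the result is a curve over wavelength whose
#' underlying lineshape is Gaussian in eV — the standard convention for
#' convolving vertical transitions.
#'
#' @param sticks A [stick_spectrum()].
#' @param fwhm_ev Full width at half maximum of the Gaussian in eV
#'   (default 0.3 eV).
#' @param grid_nm Strictly increasing wavelength grid in nm; defaults to
#'   [default_grid()].
#' @return A `broadened_spectrum`: a list with `grid_nm`, `intensity`
#'   (per-eV units so that the energy-integrated area equals the summed
#'   weights), `fwhm_ev` and `normalization` (`"none"`).
#' @export
broaden <- function(sticks, fwhm_ev = 0.3, grid_nm = default_grid(sticks)) {
  if (!inherits(sticks, "stick_spectrum")) {
    sticks <- stick_spectrum(sticks$wavelength_nm, sticks$weight)
  }
  if (!is.numeric(fwhm_ev) || length(fwhm_ev) != 1 || fwhm_ev <= 0) {
    stop("fwhm_ev must be a positive scalar", call. = FALSE)
  }
  if (length(grid_nm) == 0) stop("empty wavelength grid", call. = FALSE)
  if (any(diff(grid_nm) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  .check_wavelength(grid_nm)
  sigma <- fwhm_ev / (2 * sqrt(2 * log(2)))
  e_grid <- nm_to_ev(grid_nm)
  e_stick <- nm_to_ev(sticks$wavelength_nm)
  intensity <- numeric(length(grid_nm))
  for (i in seq_len(nrow(sticks))) {
    intensity <- intensity +
      sticks$weight[i] * stats::dnorm(e_grid, mean = e_stick[i], sd = sigma)
  }
  structure(list(grid_nm = grid_nm, intensity = intensity,
                 fwhm_ev = fwhm_ev, normalization = "none"),
            class = "broadened_spectrum")
}

#' Normalize a broadened spectrum
#'
#' @param spectrum A `broadened_spectrum`.
#' @param mode `"max"` scales the peak intensity to 1; `"area"` scales the
#'   trapezoidal area over the wavelength grid to 1.
#' @return The rescaled `broadened_spectrum` with `normalization` updated.
#' @export
normalize_spectrum <- function(spectrum, mode = c("max", "area")) {
  mode <- match.arg(mode)
  y <- spectrum$intensity
  if (all(y <= 0)) stop("spectrum has no positive intensity", call. = FALSE)
  scale <- if (mode == "max") {
    max(y)
  } else {
    x <- spectrum$grid_nm
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  spectrum$intensity <- y / scale
  spectrum$normalization <- mode
  spectrum
}

#' Relative band intensities, with and without quantum-yield correction
#'
#' Builds a comparison record for two emission bands of the same spectral
#' family: the raw oscillator-strength ratio and the quantum-yield-corrected
#' relative intensity via [intensity_scale()], both as percentages of the
#' reference band (which is 100% by construction).
#'
#' @param reference,other `rate_result` objects from
#'   [assemble_photophysics()] (or lists with fields `molecule_id`,
#'   `emission_wavelength_nm`, `oscillator_strength`, `quantum_yield`).
#' @return A data frame with rows for the reference and the other molecule
#'   and columns `molecule_id`, `oscillator_strength_percent`,
#'   `yield_corrected_percent`.
#' @export
relative_band_table <- function(reference, other) {
  if (reference$oscillator_strength <= 0) {
    stop("reference oscillator strength must be positive", call. = FALSE)
  }
  f_pct <- 100 * other$oscillator_strength / reference$oscillator_strength
  phi_pct <- intensity_scale(
    100, reference$quantum_yield, other$quantum_yield,
    reference$emission_wavelength_nm, other$emission_wavelength_nm)
  data.frame(
    molecule_id = c(reference$molecule_id, other$molecule_id),
    oscillator_strength_percent = c(100, f_pct),
    yield_corrected_percent = c(100, phi_pct),
    stringsAsFactors = FALSE
  )
}

#' Export a broadened spectrum as TSV
#'
#' Two columns (wavelength_nm, intensity) preceded by "# " comment lines
#' carrying the broadening width and normalization mode.
#'
#' @param spectrum A `broadened_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fwhm_ev: %g", spectrum$fwhm_ev),
               sprintf("# normalization: %s", spectrum$normalization),
               "wavelength_nm\tintensity"), con)
  utils::write.table(
    data.frame(spectrum$grid_nm, signif(spectrum$intensity, 10)),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.broadened_spectrum <- function(x, ...) {
  cat(sprintf(
    "Broadened spectrum: %d grid points (%g-%g nm), fwhm %g eV, normalization '%s'\n",
    length(x$grid_nm), min(x$grid_nm), max(x$grid_nm), x$fwhm_ev,
    x$normalization))
  invisible(x)
}
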