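Package: photoyield
Title: Photophysical Post-Processing of Excited-State Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns excited-state calculation outputs (emission wavelengths and
    oscillator strengths) into experimentally comparable photophysics:
    radiative rate constants from Einstein's spontaneous emission formula,
    internal-conversion rate constants from the energy-gap empirical law,
    fluorescence quantum yields, yield-corrected relative spectral
    intensities, and Gaussian-broadened theoretical spectra.  Also provides
    Hill-equation pK[a] fitting of fluorescence titration series and
    dimer-contact lifetime analysis of molecular-dynamics trajectories
    (center-of-mass distances under the minimum-image convention), together
    with readers and writers for the plain-text exchange formats involved and
    a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
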