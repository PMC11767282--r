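---
title: "From excited-state outputs to comparable spectra: the methods behind photoyield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From excited-state outputs to comparable spectra: the methods behind photoyield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoyield)
```

## The problem

A TDDFT or coupled-cluster calculation of a fluorophore yields vertical
transitions: wavelengths and oscillator strengths. A fluorimeter yields
band intensities that additionally depend on how efficiently each species
emits. For pH-responsive probes, where protonation shifts the emission and
often quenches it, comparing the two requires estimating each species'
fluorescence quantum yield and rescaling the calculated bands accordingly.
`photoyield` implements that correction chain, plus the two supporting
analyses that usually accompany such studies: Hill-equation fitting of
intensity-versus-pH titrations, and dimer-contact statistics from MD
trajectories used to rationalize quenching.

## The rate model

For an emissive S1 &rarr; S0 transition with oscillator strength $f_{21}$
and vertical emission wavelength $\lambda$ (angular frequency
$\omega_{21} = 2\pi c/\lambda$):

$$k_r = \frac{f_{21}\,\omega_{21}^2\,e^2}{2\pi\,\epsilon_0\,m\,c^3},
\qquad
k_{ic} \approx 10^{\,12 - 2\tilde\nu}\ \mathrm{s}^{-1},
\qquad
\varphi = \frac{k_r}{k_r + k_{ic}},$$

with $e$, $\epsilon_0$, $m$, $c$ fixed at CODATA-2018 values. The yield
expression assumes internal conversion dominates the non-radiative decay;
intersystem crossing is neglected, so $\varphi$ is an upper-bound style
estimate for molecules with appreciable triplet formation.

Three modelling choices deserve explanation:

- **The energy-gap argument $\tilde\nu$** is the emission energy expressed
  as a wavenumber in inverse micrometers, $1000/\lambda_{nm}$. The
  empirical constant $-2$ in the exponent belongs to that unit choice: a
  500 nm emitter has $\tilde\nu = 2$ and $k_{ic} = 10^8\,\mathrm{s^{-1}}$.
  This reading reproduces published rate constants computed from the same
  inputs to three significant figures, which eV- or cm$^{-1}$-based
  readings do not.
- **The solvent factor.** Published aqueous-solution radiative rates sit a
  consistent $\approx$1.33 below the vacuum formula applied to the same
  $(f, \lambda)$ — numerically the refractive index of water. Rather than
  silently bake either convention in, `radiative_rate()` exposes an
  explicit `solvent_factor` divisor: 1.0 (default) is the formula as
  written, 1.333 is the documented water preset used throughout the
  examples. The vacuum form is verified in the test suite against the
  standard closed-form Einstein-A restatement
  $6.6703\times10^{15} f/\lambda[\unicode{x212B}]^2$ to within 0.1% across
  200–1000 nm.
- **Absorption versus emission oscillator strengths.** The textbook
  relation $f_{12} = \tfrac13 f_{21}$ (level degeneracy) is *not* applied
  as a numeric factor anywhere: the oscillator strength from the transition
  table enters $k_r$ directly. Applying a 3 or 1/3 factor moves the rates
  well away from published values computed from the same tables, so the
  relation is treated as narrative context.

The intensity correction between two species A (reference) and B is
$I_B = I_A (\varphi_B/\varphi_A)(\lambda_A/\lambda_B)$; the wavelength
ratio converts between the photon-count and energy-flux conventions of the
two bands. `relative_band_table()` reports both the raw
oscillator-strength ratio and this corrected value as percentages of the
reference. Accuracy of the underlying electronic structure is summarized by
`mean_energy_deviation()`, the unweighted mean of
$|\lambda_{exp}/\lambda_{calc} - 1|$ — a relative *energy* deviation, since
$E \propto 1/\lambda$.

## Spectral broadening

Calculated sticks are convolved with Gaussians in energy space (the
standard convention for vertical transitions), each with area proportional
to its oscillator strength. The default FWHM is 0.3 eV — a typical width
for room-temperature solution bands — and the default grid spacing is 1 nm
spanning 100 nm beyond the bluest and reddest sticks. Because no broadening
model accompanies most published theoretical curves, the width is honest
free parameter: tests pin the properties that do not depend on it
(linearity, peak location, energy-integrated area equal to the summed
weights within quadrature error) rather than any particular figure shape.
Normalization is either peak-to-1 (`"max"`) or unit trapezoidal area over
the wavelength grid (`"area"`); both are idempotent.

## Hill-equation titration fitting

Fluorescence-versus-pH series are fitted with the four-parameter
log-logistic ("Hill") form in pH with a base-10 exponent,

$$I(\mathrm{pH}) = I_{low} + \frac{I_{high} - I_{low}}
  {1 + 10^{\,n\,(\mathrm{p}K_a - \mathrm{pH})}},$$

the standard dose-response shape for single-site titrations; rising and
falling transitions are both representable (the plateau order, aided by
the sign of $n$, carries the direction). $I(\mathrm{p}K_a)$ is the plateau
midpoint by construction. Each sigmoidal branch is fitted separately — a
probe with distinct acidic and basic transitions yields two series and two
fits; simultaneous bi-sigmoidal fitting is out of scope, as are confidence
intervals on pK~a~.

The optimizer is Levenberg–Marquardt via `minpack.lm::nls.lm`, driven
directly on the residual function rather than through the `nlsLM`/`nls`
formula interface: the formula wrappers reject exactly-sigmoidal
(zero-residual) data with a spurious singular-gradient error, and synthetic
round-trip recovery on noiseless data is part of this package's validation
contract. Convergence is the optimizer's info codes 1–3; anything else is
reported as `converged = FALSE`, never silently. Starting values are
derived from the data (plateaus from the endpoint intensities, pK~a~ from
the interpolated half-range crossing, $n = 1$), which proved robust across
the randomized validation sweep below.

## Dimer-contact analysis

Trajectories are reduced to per-molecule centers of mass; "intermolecular
distance" is the COM–COM distance under the minimum-image convention in an
orthorhombic periodic box. (Minimum atom–atom distance is a defensible
alternative that is not currently implemented; COM is the conventional
dimer metric and the one well-defined for the package's data model.) A
dimer event for a pair is a maximal run of consecutive frames below the
distance cutoff, optionally bridging up to `gap_tolerance` above-threshold
frames (default 0: strict contiguity), that lasts at least the duration
threshold. Defaults follow common strict practice: cutoff 0.7 nm, duration
0.5 ns.

Conventions that the literature leaves unstated, fixed here explicitly:

- a $k$-frame run has lifetime $k\,\Delta t$ (equivalently
  $t_{end} - t_{start} + \Delta t$) — each saved frame represents
  $\Delta t$ of residence, so a single-frame contact has lifetime
  $\Delta t$, not zero;
- lifetime dispersion uses the sample ($n-1$) standard deviation, the
  safer choice at small event counts.

Lowering the duration threshold never decreases the event count (the runs
are unchanged, only the filter widens). Loosening the distance cutoff
raises counts on diffusive trajectories — the behaviour reported for real
systems — but is not a pointwise guarantee, because widening the cutoff can
merge two events into one; the tests check the qualitative direction, not a
strict ladder.

Time-series summaries follow MD energy-analysis conventions: `rmsd` is the
root-mean-square fluctuation about the mean (population formula) and
`tot_drift` is the least-squares slope times the time span.

## The synthetic trajectory generator

`generate_synthetic_trajectory()` produces the ground-truth fixtures for
all contact-detection validation: molecules perform independent Gaussian
random walks (default step 0.15 nm/frame, reflective placement in a cubic
box) except that scripted pairs are pinned at a chosen contact distance
plus uniform jitter during their episodes. Defaults mirror a typical small
simulation setup — 5 nm cubic box, 5 ps between saved frames. What it
emulates is exactly what the detector measures: known episodes of
sub-cutoff proximity embedded in diffusive motion. What it does **not**
emulate: realistic diffusion constants, solvent structure, attractive
inter-molecular forces, or triclinic boxes. One consequence surfaces in the
tests: after a scripted episode ends the walks need a few frames to
separate the pair past the cutoff, so a detected event may slightly
outlast its scripted window; assertions bound rather than pin those
lifetimes. Passing tests therefore certify the detector and statistics, not
any claim about real association kinetics.

## Numerical and validation choices

- Constants are CODATA-2018, hard-coded; `ev_nm_product` (1239.84198
  eV·nm) is cross-checked against $hc/e$ within $10^{-6}$ relative.
- Validation problem sizes: contact detection is compared with an
  independent brute-force per-frame oracle on 100 random trajectories of
  2–10 molecules and 120–400 frames (with and without scripted episodes,
  with and without gap tolerance); Hill recovery is swept over 100 noisy
  synthetic titrations with pK~a~ $\in [2, 12]$, $|n| \in [0.5, 3]$ and
  noise up to 5% of range, requiring median pK~a~ error below 0.05. These
  sizes exercise multi-pair, multi-event bookkeeping while keeping the
  default test run fast.
- Degenerate inputs fail loudly: all-equal titration intensities, empty
  deviation lists, all-zero spectra, non-uniform frame spacing and
  incomplete trajectory frames are errors, not warnings.
- CSV round-trips are exact: missing oscillator strengths stay empty cells
  (the printed tables' "/"), wavelengths are written at full precision.

## Known limitations

- $\varphi$ ignores intersystem crossing and vibrationally resolved rates;
  no Strickler–Berg integration over the absorption band.
- The quantum-chemistry output parser is a best-effort convenience for
  simple summary blocks; the canonical exchange format is the CSV schema.
- Binary/compressed trajectory formats are not read; convert to multi-frame
  GRO or the COM CSV schema upstream.
- Broadened curves are display aids; no lineshape fitting to measured
  spectra is attempted.
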