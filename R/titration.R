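#' Construct a titration series
#'
#' A fluorescence titration series: measured intensity versus pH.
#'
#' @param ph Numeric pH values (at least 5, distinct).
#' @param intensity Non-negative fluorescence intensities (arbitrary units).
#' @param label Free-text label for the series.
#' @return A `titration_series` data frame with attribute `label`.
#' @export
titration_series <- function(ph, intensity, label = "") {
  if (length(ph) != length(intensity)) {
    stop("ph and intensity must have equal length", call. = FALSE)
  }
  if (length(ph) < 5) {
    stop("a titration series needs at least 5 points", call. = FALSE)
  }
  if (anyNA(ph) || anyNA(intensity)) stop("NA values not allowed", call. = FALSE)
  if (anyDuplicated(ph)) stop("pH values must be distinct", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  out <- data.frame(ph = ph, intensity = intensity)
  attr(out, "label") <- label
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Read a titration series from CSV
#'
#' Expects a header `ph,intensity`.
#'
#' @param path CSV file path.
#' @param label Label attached to the series (defaults to the file name).
#' @return A `titration_series`.
#' @export
read_titration_csv <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ph", "intensity") %in% names(raw))) {
    stop("titration CSV needs columns 'ph' and 'intensity'", call. = FALSE)
  }
  titration_series(as.numeric(raw$ph), as.numeric(raw$intensity), label)
}

#' Evaluate the Hill (four-parameter log-logistic) titration model
#'
#' \deqn{I(\mathrm{pH}) = I_{low} + \frac{I_{high} - I_{low}}
#'   {1 + 10^{\,n\,(\mathrm{pK_a} - \mathrm{pH})}}}
#' `intensity_low` is the plateau approached at low pH, `intensity_high`
#' the plateau at high pH; the sign of the Hill coefficient `n` encodes
#' whether intensity rises or falls through the transition. At
#' `ph == pka` the model passes through the plateau midpoint exactly.
#'
#' @param ph pH values at which to evaluate.
#' @param pka Transition midpoint.
#' @param n Hill coefficient.
#' @param intensity_low,intensity_high The two plateaus.
#' @return Model intensities.
#' @export
hill_model <- function(ph, pka, n, intensity_low, intensity_high) {
  intensity_low + (intensity_high - intensity_low) /
    (1 + 10^(n * (pka - ph)))
}

#' Fit the Hill equation to a fluorescence titration series
#'
#' Least-squares fit of [hill_model()] via Levenberg-Marquardt
#' ([minpack.lm::nls.lm()], driven directly so that exactly-sigmoidal,
#' zero-residual series converge cleanly). Deterministic given the series
#' and starting values. Default starting values: plateaus from the
#' intensities at the extreme pH points, pK_a from the pH at which the
#' intensity crosses half-range, `n = 1` (the plateau order carries the
#' transition direction; the optimizer adjusts the sign if needed).
#'
#' @param series A [titration_series()].
#' @param start Optional named list overriding the default starting values
#'   (`pka`, `n`, `intensity_low`, `intensity_high`).
#' @return A `hill_fit` list: `pka`, `hill_coefficient`, `intensity_low`,
#'   `intensity_high`, `r_squared`, `converged`, `label`.
#' @examples
#' ph <- seq(1, 6, length.out = 15)
#' s <- titration_series(ph, hill_model(ph, 3.6, 1, 1, 0))
#' fit_hill(s)$pka
#' @export
fit_hill <- function(series, start = NULL) {
  if (!inherits(series, "titration_series")) {
    series <- titration_series(series$ph, series$intensity)
  }
  y <- series$intensity
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("degenerate titration data: all intensities equal", call. = FALSE)
  }
  ord <- order(series$ph)
  ph_s <- series$ph[ord]; y_s <- y[ord]
  # default starting values
  i_lo0 <- y_s[1]; i_hi0 <- y_s[length(y_s)]
  half <- (min(y) + max(y)) / 2
  cross <- which(diff(sign(y_s - half)) != 0)
  pka0 <- if (length(cross) > 0) {
    i <- cross[1]
    # linear interpolation of the half-range crossing
    ph_s[i] + (half - y_s[i]) * (ph_s[i + 1] - ph_s[i]) / (y_s[i + 1] - y_s[i])
  } else {
    stats::median(ph_s)
  }
  n0 <- 1  # sign is carried by the plateau order in this parameterization
  st <- list(pka = pka0, n = n0, intensity_low = i_lo0, intensity_high = i_hi0)
  if (!is.null(start)) st[names(start)] <- start
  resid_fn <- function(p) {
    series$intensity - hill_model(series$ph, p[1], p[2], p[3], p[4])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(pka = st$pka, n = st$n, intensity_low = st$intensity_low,
              intensity_high = st$intensity_high),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    converged <- FALSE
    pars <- unlist(st)
  } else {
    pars <- fit$par
    # info 1-3: x-, f- or both tolerances met; anything else is failure
    converged <- fit$info %in% 1:3
  }
  pred <- hill_model(series$ph, pars[["pka"]], pars[["n"]],
                     pars[["intensity_low"]], pars[["intensity_high"]])
  r2 <- 1 - sum((y - pred)^2) / ss_tot
  structure(list(
    pka = unname(pars[["pka"]]),
    hill_coefficient = unname(pars[["n"]]),
    intensity_low = unname(pars[["intensity_low"]]),
    intensity_high = unname(pars[["intensity_high"]]),
    r_squared = r2,
    converged = converged,
    label = attr(series, "label") %||% ""
  ), class = "hill_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict intensities from a Hill fit
#'
#' @param fit A `hill_fit` from [fit_hill()].
#' @param ph pH values.
#' @return Predicted intensities.
#' @export
hill_predict <- function(fit, ph) {
  if (!isTRUE(fit$converged)) {
    stop("refusing to predict from a non-converged fit", call. = FALSE)
  }
  hill_model(ph, fit$pka, fit$hill_coefficient,
             fit$intensity_low, fit$intensity_high)
}

#' Generate a synthetic titration series
#'
#' Samples the Hill model on a pH grid and adds Gaussian noise, for fit
#' validation. Deterministic for a fixed seed.
#'
#' @param pka,n,intensity_low,intensity_high Model parameters
#'   (see [hill_model()]).
#' @param ph_range Length-2 numeric range of pH values.
#' @param n_points Number of (equally spaced) titration points.
#' @param noise_sd Standard deviation of additive Gaussian noise, as a
#'   fraction of the plateau range (0 = noiseless).
#' @param seed Integer seed for the noise.
#' @return A `titration_series`.
#' @export
simulate_titration <- function(pka, n = 1, intensity_low = 1,
                               intensity_high = 0, ph_range = c(1, 6),
                               n_points = 15, noise_sd = 0, seed = 1) {
  ph <- seq(ph_range[1], ph_range[2], length.out = n_points)
  y <- hill_model(ph, pka, n, intensity_low, intensity_high)
  if (noise_sd > 0) {
    rng <- .with_seed(seed, stats::rnorm(n_points, 0,
                                         noise_sd * abs(intensity_high - intensity_low)))
    y <- y + rng
  }
  y <- pmax(y, 0)
  titration_series(ph, y, label = sprintf("synthetic pKa=%g", pka))
}

# evaluate expr with a local RNG state so callers' streams are untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit%s: pKa = %.3f, n = %.3f, plateaus %.4g -> %.4g, R^2 = %.4f%s\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$pka, x$hill_coefficient, x$intensity_low, x$intensity_high,
    x$r_squared, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
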