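# Internal numeric helpers shared by the simulator and the quantifier.
# Keeping the line model in one place guarantees that analytic ground
# truths, window-coverage factors and simulated spectra agree exactly.

# Cumulative fraction of a unit-area absorption Lorentzian below x.
lorentz_cdf <- function(x, center, fwhm) {
  0.5 + atan(2 * (x - center) / fwhm) / pi
}

# Fraction of a unit-area Lorentzian falling inside [low, high].
lorentz_frac <- function(low, high, center, fwhm) {
  lorentz_cdf(high, center, fwhm) - lorentz_cdf(low, center, fwhm)
}

# Density of a unit-area Lorentzian at x.
lorentz_pdf <- function(x, center, fwhm) {
  (2 / (pi * fwhm)) / (1 + (2 * (x - center) / fwhm)^2)
}

# Signal a unit-area Lorentzian line contributes to the integral of
# [low, high] under the given baseline mode.  The endpoints_linear chord is
# a linear operator on the spectrum, so the measured integral decomposes
# exactly into these per-line terms: the in-window fraction minus the
# trapezoid under the chord through the line's own endpoint intensities.
line_window_signal <- function(low, high, center, fwhm,
                               baseline = "endpoints_linear") {
  frac <- lorentz_frac(low, high, center, fwhm)
  if (identical(baseline, "endpoints_linear")) {
    frac <- frac - (high - low) *
      (lorentz_pdf(low, center, fwhm) + lorentz_pdf(high, center, fwhm)) / 2
  }
  frac
}

#' First-order multiplet line positions and weights
#'
#' Expands one resonance into its component lines under the weak-coupling
#' (first-order) approximation: a singlet is one line, a doublet two lines at
#' +/- J/2, a doublet of doublets four lines at +/-(J1 +/- J2)/2, and an
#' unresolved multiplet is approximated by a Gaussian-weighted comb of
#' sub-lines spanning the stated envelope width.  Weights sum to one.
#'
#' @param center_ppm line centre (ppm)
#' @param multiplicity one of `"singlet"`, `"doublet"`, `"dd"`, `"multiplet"`
#' @param j_hz numeric vector of coupling constants (Hz); empty for singlets
#' @param width_ppm envelope FWHM (ppm) used for `"multiplet"` resonances
#' @param sf_mhz spectrometer frequency (MHz), used to convert Hz to ppm
#' @return a tibble with columns `ppm` and `weight`
#' @keywords internal
resonance_lines <- function(center_ppm, multiplicity, j_hz = numeric(),
                            width_ppm = 0.04, sf_mhz = 400) {
  j_hz <- j_hz[!is.na(j_hz)]
  if (multiplicity == "singlet") {
    return(tibble::tibble(ppm = center_ppm, weight = 1))
  }
  if (multiplicity == "doublet") {
    stopifnot(length(j_hz) >= 1)
    d <- j_hz[1] / 2 / sf_mhz
    return(tibble::tibble(ppm = center_ppm + c(-d, d), weight = c(0.5, 0.5)))
  }
  if (multiplicity == "dd") {
    stopifnot(length(j_hz) >= 2)
    d1 <- j_hz[1] / 2 / sf_mhz
    d2 <- j_hz[2] / 2 / sf_mhz
    off <- c(-d1 - d2, -d1 + d2, d1 - d2, d1 + d2)
    return(tibble::tibble(ppm = center_ppm + off, weight = rep(0.25, 4)))
  }
  if (multiplicity == "multiplet") {
    # Gaussian envelope of FWHM width_ppm, discretised as 9 sub-lines.
    sigma <- width_ppm / (2 * sqrt(2 * log(2)))
    off <- seq(-2 * sigma, 2 * sigma, length.out = 9)
    w <- stats::dnorm(off, sd = sigma)
    return(tibble::tibble(ppm = center_ppm + off, weight = w / sum(w)))
  }
  stop("unknown multiplicity: ", multiplicity, call. = FALSE)
}

# Trapezoidal integral of y over x (x need not be equally spaced).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Robust noise estimate (standard-deviation scale) from a vector.
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

`%||%` <- function(a, b) if (is.null(a)) b else a
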