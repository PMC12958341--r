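#' Free induction decay container
#'
#' @param points complex time-domain samples
#' @param dwell_s dwell time (seconds per point)
#' @param sf_mhz spectrometer 1H frequency (MHz)
#' @param carrier_ppm transmitter offset (ppm); the spectral window is
#'   centred here after Fourier transform
#' @param n_scans number of co-added scans (metadata only)
#' @return an object of class `qnmr_fid`
#' @export
new_fid <- function(points, dwell_s, sf_mhz, carrier_ppm = 5, n_scans = 1) {
  if (length(points) == 0) stop("FID must be non-empty", call. = FALSE)
  if (dwell_s <= 0) stop("dwell_s must be > 0", call. = FALSE)
  if (sf_mhz <= 0) stop("sf_mhz must be > 0", call. = FALSE)
  structure(
    list(points = as.complex(points), dwell_s = dwell_s, sf_mhz = sf_mhz,
         carrier_ppm = carrier_ppm, n_scans = n_scans),
    class = "qnmr_fid"
  )
}

#' @export
print.qnmr_fid <- function(x, ...) {
  cat(sprintf("<qnmr_fid> %d points, dwell %.3g s (sw %.0f Hz), sf %.1f MHz, carrier %.2f ppm, %d scan(s)\n",
              length(x$points), x$dwell_s, 1 / x$dwell_s, x$sf_mhz,
              x$carrier_ppm, x$n_scans))
  invisible(x)
}

#' Frequency-domain spectrum container
#'
#' A spectrum is a tibble with columns `ppm` (strictly descending, the NMR
#' plotting convention) and `intensity` (real absorption-mode signal), plus
#' `sf_mhz` and a `provenance` list carried as attributes.  Being a tibble,
#' it pipes directly into dplyr/ggplot2 workflows.
#'
#' @param ppm chemical-shift axis (any strict monotone order; stored descending)
#' @param intensity real intensities, same length as `ppm`
#' @param sf_mhz spectrometer frequency (MHz); `NA` if unknown
#' @param provenance named list logging processing steps
#' @return an object of class `qnmr_spectrum` (a tibble)
#' @export
new_spectrum <- function(ppm, intensity, sf_mhz = NA_real_, provenance = list()) {
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have the same length", call. = FALSE)
  }
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  if (length(d) && all(d > 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  class(out) <- c("qnmr_spectrum", class(out))
  attr(out, "sf_mhz") <- sf_mhz
  attr(out, "provenance") <- provenance
  out
}

#' Spectrometer frequency of a spectrum
#' @param spec a `qnmr_spectrum`
#' @return frequency in MHz (may be `NA`)
#' @export
sf_mhz <- function(spec) attr(spec, "sf_mhz")

#' Processing provenance of a spectrum
#' @param spec a `qnmr_spectrum`
#' @return named list of processing parameters applied so far
#' @export
provenance <- function(spec) attr(spec, "provenance")

#' Process an FID into an absorption-mode spectrum
#'
#' Applies exponential apodization `exp(-pi * lb * t)` (line broadening `lb`
#' in Hz), halves the first point (one-sided DFT convention, removes the
#' constant baseline offset), zero-fills (each level doubles the length),
#' Fourier transforms, and applies a zero-order phase chosen so the tallest
#' peak is pure absorption.  A noise-free on-resonance exponential therefore
#' yields an absorption Lorentzian of FWHM `r2 + lb` Hz.
#'
#' @param fid a `qnmr_fid`
#' @param line_broadening_hz exponential line broadening (Hz, >= 0)
#' @param zero_fill_levels number of length-doublings before the FFT (>= 0)
#' @return a `qnmr_spectrum` with processing recorded in its provenance
#' @export
process_fid <- function(fid, line_broadening_hz = 0.3, zero_fill_levels = 1) {
  stopifnot(inherits(fid, "qnmr_fid"))
  if (line_broadening_hz < 0) stop("line_broadening_hz must be >= 0", call. = FALSE)
  if (zero_fill_levels < 0 || zero_fill_levels != round(zero_fill_levels)) {
    stop("zero_fill_levels must be a non-negative integer", call. = FALSE)
  }
  n <- length(fid$points)
  t <- (seq_len(n) - 1) * fid$dwell_s
  x <- fid$points * exp(-pi * line_broadening_hz * t)
  x[1] <- x[1] / 2
  nz <- n * 2^zero_fill_levels
  x <- c(x, complex(real = rep(0, nz - n)))
  s <- stats::fft(x)
  # Reorder so the axis runs from -sw/2 to +sw/2 around the carrier.
  half <- nz %/% 2
  s <- c(s[(half + 1):nz], s[1:half])
  freq_hz <- (seq_len(nz) - 1 - half) / (nz * fid$dwell_s)
  # Zero-order phase from the tallest peak.
  k <- which.max(Mod(s))
  phi <- if (Mod(s[k]) > 0) Arg(s[k]) else 0
  s <- s * exp(complex(imaginary = -phi))
  ppm <- fid$carrier_ppm + freq_hz / fid$sf_mhz
  new_spectrum(
    ppm, Re(s), sf_mhz = fid$sf_mhz,
    provenance = list(
      line_broadening_hz = line_broadening_hz,
      zero_fill_levels = zero_fill_levels,
      phase0_rad = phi,
      dwell_s = fid$dwell_s,
      n_points = n,
      calibration_shift_ppm = 0
    )
  )
}

#' Calibrate the ppm axis against a reference peak
#'
#' Rigidly shifts the axis so that the maximum-intensity point inside
#' `search_window` lands exactly on `reference_ppm` (standard internal-
#' standard referencing).  The applied shift is appended to the provenance.
#'
#' @param spec a `qnmr_spectrum`
#' @param reference_ppm target shift for the reference peak (ppm)
#' @param search_window length-2 numeric, window searched for the peak
#' @param noise_region length-2 numeric, signal-free region used for the
#'   noise estimate (default 9.5-10 ppm)
#' @param snr_min minimum peak height, in noise standard deviations, for the
#'   reference peak to count as detected
#' @return the calibrated `qnmr_spectrum`
#' @export
calibrate_ppm <- function(spec, reference_ppm, search_window,
                          noise_region = c(9.5, 10), snr_min = 5) {
  stopifnot(inherits(spec, "qnmr_spectrum"))
  lo <- min(search_window); hi <- max(search_window)
  if (lo < min(spec$ppm) || hi > max(spec$ppm)) {
    stop("search window outside the spectral axis", call. = FALSE)
  }
  idx <- which(spec$ppm >= lo & spec$ppm <= hi)
  if (length(idx) < 3) stop("search window spans too few points", call. = FALSE)
  noise <- spectrum_noise(spec, noise_region)
  win <- spec$intensity[idx]
  k <- idx[which.max(win)]
  height <- spec$intensity[k] - stats::median(win)
  if (height <= snr_min * noise) {
    stop("no reference peak above the noise threshold in the search window",
         call. = FALSE)
  }
  shift <- reference_ppm - spec$ppm[k]
  prov <- attr(spec, "provenance")
  prov$calibration_shift_ppm <- (prov$calibration_shift_ppm %||% 0) + shift
  new_spectrum(spec$ppm + shift, spec$intensity, sf_mhz = attr(spec, "sf_mhz"),
               provenance = prov)
}

# Noise scale of a spectrum, from a nominally signal-free region; falls back
# to a small fraction of the maximum intensity so that thresholds remain
# meaningful for noise-free synthetic spectra.
spectrum_noise <- function(spec, noise_region = c(9.5, 10)) {
  lo <- min(noise_region); hi <- max(noise_region)
  idx <- which(spec$ppm >= lo & spec$ppm <= hi)
  est <- if (length(idx) >= 8) robust_sd(spec$intensity[idx]) else 0
  floor_est <- 1e-4 * max(abs(spec$intensity), 0)
  max(est, floor_est)
}

#' Integrate a ppm window
#'
#' Trapezoidal integration of the intensity over a closed ppm window, with
#' an optional local linear baseline drawn through the window endpoints
#' (`endpoints_linear`, the default, which removes constant and linear
#' backgrounds such as broad oligomer humps).  The sign of the signal is
#' preserved.  Units are intensity x ppm.
#'
#' @param spec a `qnmr_spectrum`
#' @param window length-2 numeric ppm interval
#' @param baseline `"endpoints_linear"` or `"none"`
#' @param min_points smallest acceptable number of digital points in the
#'   window; fewer is an error (guards against under-sampled integrals)
#' @return the integral (intensity x ppm)
#' @export
integrate_region <- function(spec, window,
                             baseline = c("endpoints_linear", "none"),
                             min_points = 2) {
  stopifnot(inherits(spec, "qnmr_spectrum"))
  baseline <- match.arg(baseline)
  lo <- min(window); hi <- max(window)
  if (lo < min(spec$ppm) || hi > max(spec$ppm)) {
    stop(sprintf("window [%.4f, %.4f] outside the spectral axis [%.4f, %.4f]",
                 lo, hi, min(spec$ppm), max(spec$ppm)), call. = FALSE)
  }
  idx <- which(spec$ppm >= lo & spec$ppm <= hi)
  if (length(idx) < min_points) {
    stop(sprintf("window [%.4f, %.4f] spans only %d point(s); >= %d required",
                 lo, hi, length(idx), min_points), call. = FALSE)
  }
  x <- spec$ppm[idx]
  y <- spec$intensity[idx]
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (baseline == "endpoints_linear") {
    n <- length(x)
    base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
    y <- y - base
  }
  trapz(x, y)
}

#' @export
print.qnmr_spectrum <- function(x, ...) {
  cat(sprintf("<qnmr_spectrum> %d points, %.2f to %.2f ppm, sf %s MHz\n",
              nrow(x), max(x$ppm), min(x$ppm),
              ifelse(is.na(attr(x, "sf_mhz")), "?", format(attr(x, "sf_mhz")))))
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("  provenance:", paste(names(prov), unlist(lapply(prov, format)),
                               sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}
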