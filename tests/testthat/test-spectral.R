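# Single decaying complex exponential: closed-form absorption Lorentzian.
one_line_fid <- function(offset_hz, r2_hz, amp = 1, aq = 2, sw_hz = 4000,
                         sf = 400) {
  dwell <- 1 / sw_hz
  t <- (seq_len(round(aq / dwell)) - 1) * dwell
  new_fid(amp * exp(complex(imaginary = 2 * pi * offset_hz * t) - pi * r2_hz * t),
          dwell_s = dwell, sf_mhz = sf, carrier_ppm = 5)
}

fwhm_of <- function(spec) {
  k <- which.max(spec$intensity)
  half <- spec$intensity[k] / 2
  x <- rev(spec$ppm); y <- rev(spec$intensity)  # ascending
  k <- which.max(y)
  left <- max(which(y[1:k] <= half))
  right <- k - 1 + min(which(y[k:length(y)] <= half))
  xi_l <- x[left] + (x[left + 1] - x[left]) * (half - y[left]) / (y[left + 1] - y[left])
  xi_r <- x[right - 1] + (x[right] - x[right - 1]) * (half - y[right - 1]) /
    (y[right] - y[right - 1])
  xi_r - xi_l
}

test_that("all-zero FID processes to an all-zero spectrum", {
  fid <- new_fid(complex(real = rep(0, 256)), dwell_s = 1e-3, sf_mhz = 400)
  spec <- process_fid(fid, 0.3, 1)
  expect_equal(nrow(spec), 512)
  expect_true(all(spec$intensity == 0))
  expect_error(new_fid(complex(0), 1e-3, 400), "non-empty")
})

test_that("a decaying exponential gives a Lorentzian at the right place and width", {
  r2 <- 2; lb <- 0.3; off <- 120
  spec <- process_fid(one_line_fid(off, r2), lb, 1)
  k <- which.max(spec$intensity)
  expect_equal(spec$ppm[k], 5 + off / 400, tolerance = 1e-3)
  # FWHM = (r2 + lb)/pi * pi ... = r2 + lb Hz, within 5%
  expect_equal(fwhm_of(spec) * 400, r2 + lb, tolerance = 0.05)
  # peak is absorption-phased: symmetric about the maximum
  l <- spec$intensity[k + 10]; r <- spec$intensity[k - 10]
  expect_equal(l, r, tolerance = 0.05)
})

test_that("zero-filling leaves window integrals unchanged within 1%", {
  fid <- one_line_fid(80, 1.5)
  s0 <- process_fid(fid, 0.3, 0)
  s1 <- process_fid(fid, 0.3, 1)
  w <- c(5 + 80 / 400 - 0.05, 5 + 80 / 400 + 0.05)
  i0 <- integrate_region(s0, w, baseline = "none")
  i1 <- integrate_region(s1, w, baseline = "none")
  expect_equal(i1 / i0, 1, tolerance = 0.01)
})

test_that("total spectral integral is conserved from the first apodized point", {
  fid <- one_line_fid(37, 1.2, amp = 2.5)
  lb <- 0.3
  spec <- process_fid(fid, lb, 1)
  df_ppm <- abs(diff(spec$ppm[1:2]))
  total <- sum(spec$intensity) * df_ppm
  # first apodized, halved point over dwell, per ppm
  expected <- Re(fid$points[1] / 2) / fid$dwell_s / fid$sf_mhz
  expect_equal(total, expected, tolerance = 1e-6)
})

test_that("unit Lorentzian window integral matches the analytic CDF fraction", {
  r2 <- 1.5; lb <- 0.5
  spec <- process_fid(one_line_fid(0, r2, aq = 4), lb, 1)
  fwhm_ppm <- (r2 + lb) / 400
  c0 <- 5
  w <- c(c0 - 20 * fwhm_ppm, c0 + 20 * fwhm_ppm)
  part <- integrate_region(spec, w, baseline = "none")
  total <- sum(spec$intensity) * abs(diff(spec$ppm[1:2]))
  expect_equal(part / total, (2 / pi) * atan(40), tolerance = 0.01)
})

test_that("integration is linear and endpoint baseline kills constants", {
  spec <- process_fid(one_line_fid(50, 2), 0.3, 0)
  spec3 <- new_spectrum(spec$ppm, 3 * spec$intensity, sf_mhz = 400)
  w <- c(5.05, 5.25)
  expect_equal(integrate_region(spec3, w, baseline = "none"),
               3 * integrate_region(spec, w, baseline = "none"))
  flat <- new_spectrum(seq(10, 0, length.out = 1001), rep(7, 1001), sf_mhz = 400)
  expect_equal(integrate_region(flat, c(2, 4), baseline = "endpoints_linear"), 0)
  expect_equal(integrate_region(new_spectrum(seq(10, 0, length.out = 101),
                                             rep(0, 101)), c(1, 3)), 0)
  expect_error(integrate_region(spec, c(90, 95)), "outside")
  expect_error(integrate_region(spec, c(5.0001, 5.0002), min_points = 8),
               "point")
})

test_that("ppm calibration finds and corrects a rigid shift", {
  spec <- process_fid(one_line_fid(0, 1), 0.3, 1)  # peak at 5 ppm
  shifted <- new_spectrum(spec$ppm + 0.02, spec$intensity, sf_mhz = 400,
                          provenance = provenance(spec))
  cal <- calibrate_ppm(shifted, 5, c(4.9, 5.1))
  step <- abs(diff(spec$ppm[1:2]))
  expect_lt(abs(cal$ppm[which.max(cal$intensity)] - 5), step / 2)
  expect_equal(provenance(cal)$calibration_shift_ppm, -0.02, tolerance = step)
  aligned <- calibrate_ppm(spec, spec$ppm[which.max(spec$intensity)],
                           c(4.9, 5.1))
  expect_equal(provenance(aligned)$calibration_shift_ppm, 0)
  flat <- new_spectrum(seq(10, 0, length.out = 2001), rep(0, 2001), sf_mhz = 400)
  expect_error(calibrate_ppm(flat, 5, c(4.5, 5.5)), "noise")
})

test_that("two-column text spectra round-trip; ascending input is reversed", {
  spec <- quick_spec(c(PS = 0.3))$spec
  sub <- new_spectrum(spec$ppm[spec$ppm > 6 & spec$ppm < 7],
                      spec$intensity[spec$ppm > 6 & spec$ppm < 7],
                      sf_mhz = 400)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sub, path)
  back <- suppressWarnings(read_spectrum(path))
  expect_equal(back$ppm, sub$ppm, tolerance = 1e-7)
  expect_equal(back$intensity, sub$intensity, tolerance = 1e-7)
  expect_true(is.na(sf_mhz(back)))
  # ascending two-column input comes back descending with reversed intensity
  asc <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# ppm intensity", "1.0 10", "2.0 20", "3.0 30"), asc)
  sp <- suppressWarnings(read_spectrum(asc))
  expect_equal(sp$ppm, c(3, 2, 1))
  expect_equal(sp$intensity, c(30, 20, 10))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0 10", "2.0 oops"), bad)
  expect_error(suppressWarnings(read_spectrum(bad)), "line 2")
})

test_that("JCAMP-DX files from the simulator round-trip within representation precision", {
  spec <- quick_spec(c(PS = 0.3, PG = 0.2))$spec
  keep <- spec$ppm > 6 & spec$ppm < 8
  sub <- new_spectrum(spec$ppm[keep], spec$intensity[keep], sf_mhz = 400)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(sub, path)
  back <- read_spectrum(path)
  expect_equal(sf_mhz(back), 400)
  expect_equal(back$ppm, sub$ppm, tolerance = 1e-8)
  expect_equal(max(abs(back$intensity - sub$intensity)),
               0, tolerance = 1e-8 * max(abs(sub$intensity)))
  truncated <- withr::local_tempfile(fileext = ".jdx")
  writeLines(readLines(path)[1:10], truncated)
  expect_error(read_spectrum(truncated), "XYDATA|NPOINTS")
})
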