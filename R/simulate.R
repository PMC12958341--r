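#' Specify a synthetic mixture
#'
#' Describes a model RCF-oil NMR sample: which compounds are dissolved in
#' the tube at which concentrations, how much internal standard was weighed
#' in, and the acquisition settings of the virtual spectrometer.  Defaults
#' mirror the reference sample preparation (1 mg/mL TTB in a 1 mL
#' reconstitution) and an acquisition giving 0.25 Hz/point digital
#' resolution after one level of zero-filling.
#'
#' @param members data frame with columns `abbrev` and `conc_mg_ml`
#'   (concentration in the tube, mg/mL); the internal standard is added
#'   separately and must not appear here
#' @param is_mass_mg internal-standard (TTB) mass in the tube (mg)
#' @param volume_ml reconstitution volume (mL)
#' @param noise_sigma standard deviation of the additive complex Gaussian
#'   FID noise (per real/imaginary component, per point)
#' @param seed integer seed for the noise
#' @param sf_mhz spectrometer 1H frequency (MHz)
#' @param aq_s acquisition time (s)
#' @param r2_hz natural linewidth parameter: every line decays at
#'   `pi * r2_hz` so its unapodized FWHM is `r2_hz` Hz
#' @param carrier_ppm centre of the spectral window (ppm)
#' @param sw_ppm spectral width (ppm)
#' @return an object of class `qnmr_mixture`
#' @export
mixture_spec <- function(members, is_mass_mg = 1, volume_ml = 1,
                         noise_sigma = 0, seed = 1L, sf_mhz = 400,
                         aq_s = 2, r2_hz = 1, carrier_ppm = 5, sw_ppm = 20) {
  members <- tibble::as_tibble(members)
  stopifnot(all(c("abbrev", "conc_mg_ml") %in% names(members)))
  if (any(members$conc_mg_ml < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (volume_ml <= 0) stop("volume_ml must be > 0", call. = FALSE)
  if (r2_hz <= 0) stop("r2_hz must be > 0", call. = FALSE)
  if ("TTB" %in% members$abbrev) {
    stop("the internal standard is specified via is_mass_mg, not as a member",
         call. = FALSE)
  }
  structure(
    list(members = members, is_mass_mg = is_mass_mg, volume_ml = volume_ml,
         noise_sigma = noise_sigma, seed = as.integer(seed), sf_mhz = sf_mhz,
         aq_s = aq_s, r2_hz = r2_hz, carrier_ppm = carrier_ppm,
         sw_ppm = sw_ppm),
    class = "qnmr_mixture"
  )
}

# Amplitude scale: FID amplitude per (mmol/mL of protons) per line-weight.
SIM_AMP_SCALE <- 1000

# All spectral lines of a mixture: one row per component line with its FID
# amplitude.  TTB is included from is_mass_mg.
mixture_lines <- function(mix, panel) {
  members <- mix$members[mix$members$conc_mg_ml > 0, , drop = FALSE]
  members <- dplyr::bind_rows(
    members[, c("abbrev", "conc_mg_ml")],
    tibble::tibble(abbrev = "TTB",
                   conc_mg_ml = mix$is_mass_mg / mix$volume_ml)
  )
  unknown <- setdiff(members$abbrev, panel$compounds$abbrev)
  if (length(unknown)) {
    stop("unknown compound(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(members)), function(i) {
    ab <- members$abbrev[i]
    cmp <- get_compound(panel, ab)
    cmol <- members$conc_mg_ml[i] / cmp$molar_mass  # mmol/mL
    rr <- cmp$resonances
    purrr::map_dfr(seq_len(nrow(rr)), function(k) {
      ln <- resonance_lines(rr$center_ppm[k], rr$multiplicity[k],
                            rr$j_hz[[k]], rr$width_ppm[k], mix$sf_mhz)
      tibble::tibble(
        abbrev = ab, label = rr$label[k], ppm = ln$ppm,
        amp = SIM_AMP_SCALE * cmol * rr$n_protons[k] * ln$weight
      )
    })
  })
}

#' Simulate the FID of a defined mixture
#'
#' Builds a first-order (weak-coupling) stick spectrum from every resonance
#' of every mixture member (plus the internal standard), and synthesises the
#' complex FID as a sum of exponentially decaying oscillators with decay
#' rate `pi * r2_hz`, so each line is Lorentzian with FWHM `r2_hz` Hz before
#' apodization.  Line amplitudes are proportional to molar concentration
#' times proton count divided over the multiplet lines.  Seeded complex
#' Gaussian noise is added point-wise.
#'
#' The returned ground truth carries true concentrations and masses and, for
#' every panel window, the analytic integral (intensity x ppm) that the
#' default processing (`lb_hz` line broadening) would place inside that
#' window, summed over all lines of all compounds -- overlaps included, so
#' correction rules can be validated exactly.
#'
#' @param mix a `qnmr_mixture`
#' @param panel a `qnmr_panel`
#' @param lb_hz line broadening assumed when computing analytic window
#'   integrals (match the value later passed to [process_fid()])
#' @return a list with elements `fid` (a `qnmr_fid`) and `truth` (a list
#'   with tibbles `compounds` and `windows`)
#' @export
simulate_fid <- function(mix, panel = default_panel(), lb_hz = 0.3) {
  stopifnot(inherits(mix, "qnmr_mixture"))
  dwell <- 1 / (mix$sw_ppm * mix$sf_mhz)
  n <- round(mix$aq_s / dwell)
  t <- (seq_len(n) - 1) * dwell
  lines <- mixture_lines(mix, panel)
  sig <- complex(real = rep(0, n))
  lambda <- pi * mix$r2_hz
  for (i in seq_len(nrow(lines))) {
    f <- (lines$ppm[i] - mix$carrier_ppm) * mix$sf_mhz
    sig <- sig + lines$amp[i] * exp(complex(imaginary = 2 * pi * f * t) - lambda * t)
  }
  if (mix$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(mix$seed)
    sig <- sig + complex(real = stats::rnorm(n, 0, mix$noise_sigma),
                         imaginary = stats::rnorm(n, 0, mix$noise_sigma))
  }
  fid <- new_fid(sig, dwell_s = dwell, sf_mhz = mix$sf_mhz,
                 carrier_ppm = mix$carrier_ppm, n_scans = 32)
  truth <- ground_truth(mix, panel, lines, dwell, lb_hz)
  list(fid = fid, truth = truth)
}

# Analytic ground truth for a simulated mixture.
ground_truth <- function(mix, panel, lines, dwell, lb_hz) {
  compounds <- dplyr::left_join(
    mix$members, panel$compounds[, c("abbrev", "molar_mass", "cls")],
    by = "abbrev"
  )
  compounds$mass_mg <- compounds$conc_mg_ml * mix$volume_ml
  fwhm_ppm <- (mix$r2_hz + lb_hz) / mix$sf_mhz
  # Integral (intensity x ppm) of a full line of FID amplitude A is
  # A / (2 * dwell * sf): the one-sided FT of A*exp(-lambda t) has real-part
  # area A/2 over Hz, and the DFT scales intensities by 1/dwell.
  area_scale <- 1 / (2 * dwell * mix$sf_mhz)
  win <- panel$resonances[, c("abbrev", "label", "window_low", "window_high")]
  win$true_integral <- vapply(seq_len(nrow(win)), function(i) {
    sum(lines$amp * area_scale *
          lorentz_frac(win$window_low[i], win$window_high[i], lines$ppm,
                       fwhm_ppm))
  }, numeric(1))
  list(
    compounds = tibble::as_tibble(compounds),
    windows = tibble::as_tibble(win),
    fwhm_ppm = fwhm_ppm,
    area_scale = area_scale
  )
}

# Scenario concentration tables (mg/mL in the tube).  With the default
# sample preparation (0.5 mL aliquot of 50 mL liquor, 400 mg lignin basis)
# 1 mg/mL in the tube corresponds to a 25 wt% yield, so these land at
# typical published yields for each selectivity regime.
OIL_SCENARIOS <- list(
  propyl_selective = c(PS = 8.2, PSOH = 3.8, PG = 5.26, PGOH = 2.9,
                       PES = 0.79, PEG = 0.22, ES = 0.25,
                       PHBA = 1.2, MP = 0.6),
  mixed_50_50 = c(PS = 4.5, PSOH = 4.7, PG = 3.0, PGOH = 3.1,
                  PES = 0.3, PEG = 0.1, ES = 0.2, EG = 0.1,
                  PHBA = 1.0, MP = 0.5),
  oh_selective = c(PS = 0.5, PSOH = 10.0, PG = 0.3, PGOH = 5.6,
                   ES = 0.05, EG = 0.02, PHBA = 0.3, MP = 0.15),
  h2free_propenyl = c(PES = 5.5, PEG = 3.5, PS = 0.2, PG = 0.2,
                      PSOH = 0.1, PGOH = 0.1, PHBA = 1.5, MP = 0.3),
  pdc_three_chain = c(PS = 3.0, PSOH = 3.0, ES = 2.5, PG = 2.0,
                      PGOH = 2.2, EG = 1.6, PHBA = 1.0, MP = 0.3,
                      PHENOL = 1.2),
  phenol_rich = c(PS = 4.0, PSOH = 2.0, PG = 2.5, PGOH = 1.5,
                  PES = 0.3, PEG = 0.15, ES = 0.2, EG = 0.15,
                  PHBA = 2.0, MP = 0.5, PHENOL = 3.0)
)

#' Names of the built-in oil scenarios
#' @return character vector of scenario names
#' @export
oil_scenarios <- function() names(OIL_SCENARIOS)

#' Simulate a preset RCF-oil selectivity regime
#'
#' Six presets emulate the selectivity regimes seen across RCF conditions:
#' `propyl_selective` (high 4-propyl selectivity with a roughly 2:1 PS:PSOH
#' split), `mixed_50_50` (balanced 4-propyl/4-(3-hydroxypropyl)),
#' `oh_selective` (over 90% 4-(3-hydroxypropyl)), `h2free_propenyl`
#' (dominated by the 4-propenyl monomers PES/PEG, with only traces of
#' PS/PG), `pdc_three_chain` (ethyl, propyl and hydroxypropyl side chains
#' co-produced, with phenol present, the hard case for the G2 region), and
#' `phenol_rich` (phenol overlapping the whole G2 region).  Yields are
#' stated per 400 mg of lignin in the charged biomass under the default
#' [sample_prep()].
#'
#' @param scenario one of [oil_scenarios()]
#' @param seed integer noise seed
#' @param panel a `qnmr_panel`
#' @param noise_sigma FID noise level; the default gives spectrum
#'   signal-to-noise well above 50 for monomers at or above roughly
#'   0.2 wt% yield
#' @param scale multiply every monomer concentration (the internal standard
#'   is unchanged)
#' @param ... further arguments passed to [mixture_spec()]
#' @return a list with elements `fid`, `truth` and `mixture`
#' @export
simulate_oil <- function(scenario = oil_scenarios(), seed = 1L,
                         panel = default_panel(), noise_sigma = 0.05,
                         scale = 1, ...) {
  scenario <- match.arg(scenario)
  conc <- OIL_SCENARIOS[[scenario]] / 25 * scale  # wt% -> mg/mL in tube
  mix <- mixture_spec(
    tibble::tibble(abbrev = names(conc), conc_mg_ml = unname(conc)),
    noise_sigma = noise_sigma, seed = seed, ...
  )
  out <- simulate_fid(mix, panel)
  out$mixture <- mix
  out$scenario <- scenario
  out
}

#' Random mixtures spanning the selectivity regimes
#'
#' Draws `n` mixtures by cycling through the built-in scenarios and
#' jittering every concentration by an independent uniform factor
#' `1 +/- jitter`.  Used for parameter-recovery studies.
#'
#' @param n number of mixtures
#' @param seed integer seed controlling both the jitter and the per-mixture
#'   noise seeds
#' @param jitter half-width of the uniform concentration jitter
#' @return a list of `qnmr_mixture` objects, each with a `scenario`
#'   attribute
#' @export
random_oil_mixtures <- function(n, seed = 1L, jitter = 0.3) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  scen <- rep(names(OIL_SCENARIOS), length.out = n)
  lapply(seq_len(n), function(i) {
    conc <- OIL_SCENARIOS[[scen[i]]] / 25
    conc <- conc * stats::runif(length(conc), 1 - jitter, 1 + jitter)
    mix <- mixture_spec(
      tibble::tibble(abbrev = names(conc), conc_mg_ml = unname(conc)),
      noise_sigma = 0.05, seed = seed + i
    )
    attr(mix, "scenario") <- scen[i]
    mix
  })
}
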