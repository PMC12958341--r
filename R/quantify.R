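#' Sample preparation record
#'
#' Captures the numbers that turn a mass in the NMR tube into a whole-
#' reaction wt% yield: the aliquot of reaction liquor dried into the tube,
#' the total liquor volume, the weighed internal-standard mass, and the
#' yield basis mass (the lignin content of the charged biomass).  The yield
#' convention is
#' `yield_wt_pct = 100 * mass_in_tube * (total_liquor_ml / aliquot_ml) / basis_mass_mg`.
#'
#' @param aliquot_ml liquor volume dried into the tube (mL)
#' @param total_liquor_ml total reaction liquor volume (mL)
#' @param is_mass_mg internal-standard (TTB) mass in the tube (mg)
#' @param basis_mass_mg yield denominator (mg); document what it is --
#'   conventionally Klason lignin in the charged biomass
#' @return an object of class `qnmr_prep`
#' @export
sample_prep <- function(aliquot_ml = 0.5, total_liquor_ml = 50,
                        is_mass_mg = 1, basis_mass_mg = 400) {
  vals <- c(aliquot_ml, total_liquor_ml, is_mass_mg, basis_mass_mg)
  if (any(vals <= 0)) stop("all sample-prep quantities must be > 0", call. = FALSE)
  if (aliquot_ml > total_liquor_ml) {
    stop("aliquot_ml cannot exceed total_liquor_ml", call. = FALSE)
  }
  structure(list(aliquot_ml = aliquot_ml, total_liquor_ml = total_liquor_ml,
                 is_mass_mg = is_mass_mg, basis_mass_mg = basis_mass_mg),
            class = "qnmr_prep")
}

yield_from_mass <- function(mass_mg, prep) {
  100 * mass_mg * (prep$total_liquor_ml / prep$aliquot_ml) / prep$basis_mass_mg
}

#' Analyte mass from internal-standard ratio
#'
#' The standard qNMR relation: per-proton integrals are proportional to
#' molar amounts, so
#' `m_a = (i_a / i_is) * (n_is / n_a) * (mw_a / mw_is) * m_is`.
#'
#' @param i_a analyte integral
#' @param i_is internal-standard integral (must be > 0)
#' @param n_a,n_is proton counts behind the two integrals
#' @param mw_a,mw_is molar masses (g/mol)
#' @param m_is internal-standard mass (mg)
#' @return analyte mass in the same units as `m_is`
#' @export
mass_from_integral <- function(i_a, i_is, n_a, n_is, mw_a, mw_is, m_is) {
  if (any(i_is <= 0)) {
    stop("internal-standard integral must be > 0; quantification impossible",
         call. = FALSE)
  }
  if (any(c(n_a, n_is, mw_a, mw_is, m_is) <= 0)) {
    stop("proton counts, molar masses and m_is must be > 0", call. = FALSE)
  }
  (i_a / i_is) * (n_is / n_a) * (mw_a / mw_is) * m_is
}

#' Correct the PG G2 integral for PEG overlap
#'
#' The G5 doublet-of-doublets of 4-propenylguaiacol (PEG, isoeugenol) sits
#' half inside the PG G2 window, so 50% of the PEG G2 integral is
#' subtracted from the raw PG G2 integral.  The result is floored at zero;
#' a flooring event is flagged via the `"floored"` attribute.
#'
#' @param i_pg_g2 raw PG G2 integral (>= 0)
#' @param i_peg_g2 PEG G2 integral (>= 0)
#' @return corrected integral, with attribute `floored`
#' @export
correct_pg_integral <- function(i_pg_g2, i_peg_g2) {
  if (i_pg_g2 < 0 || i_peg_g2 < 0) stop("integrals must be >= 0", call. = FALSE)
  v <- i_pg_g2 - 0.5 * i_peg_g2
  out <- max(v, 0)
  attr(out, "floored") <- v < 0
  out
}

#' Estimate the EG yield from ES and the PS/PG ratio
#'
#' EG cannot be integrated directly (its G2 lies under the PGOH G2 window),
#' so its yield is estimated by assuming the ethyl products follow the same
#' S/G split as the propyl products: `eg = es * (pg / ps)`.
#'
#' @param es_yield ES yield (wt%)
#' @param ps_yield PS yield (wt%); must be > 0
#' @param pg_yield PG yield (wt%)
#' @return estimated EG yield (wt%); always an estimate, never a direct
#'   quantification
#' @export
estimate_eg_yield <- function(es_yield, ps_yield, pg_yield) {
  if (ps_yield <= 0) {
    stop("PS yield must be > 0 to estimate EG; EG not quantified", call. = FALSE)
  }
  es_yield * (pg_yield / ps_yield)
}

# ---------------------------------------------------------------------------
# Shared quantification context: TTB integral, linewidth estimate, per-proton
# area scale, and the analytic TTB tail-leakage correction.

# Fraction of a compound's primary-resonance area contributing to the
# baseline-corrected integral of a window, given an effective Lorentzian
# FWHM (ppm).
window_coverage <- function(panel, abbrev, low, high, fwhm_ppm, sf,
                            baseline = "endpoints_linear") {
  pr <- primary_resonance(panel, abbrev)
  ln <- resonance_lines(pr$center_ppm, pr$multiplicity, pr$j_hz[[1]],
                        pr$width_ppm, sf)
  sum(ln$weight * line_window_signal(low, high, ln$ppm, fwhm_ppm, baseline))
}

quant_context <- function(spec, panel, baseline = "endpoints_linear",
                          noise_region = c(9.5, 10), is_mass_mg = 1,
                          ttb_snr_min = 20) {
  sf <- attr(spec, "sf_mhz")
  sf_defaulted <- is.na(sf)
  if (sf_defaulted) sf <- 400
  noise <- spectrum_noise(spec, noise_region)
  ttb <- get_compound(panel, "TTB")
  pr <- primary_resonance(panel, "TTB")
  i_ttb_raw <- integrate_region(spec, c(pr$window_low, pr$window_high),
                                baseline = baseline, min_points = 8)
  idx <- which(spec$ppm >= pr$window_low & spec$ppm <= pr$window_high)
  win <- spec$intensity[idx]
  height <- max(win) - (win[1] + win[length(win)]) / 2
  if (i_ttb_raw <= 0 || height <= ttb_snr_min * noise) {
    stop("internal standard (TTB) not detected; cannot quantify", call. = FALSE)
  }
  # Effective Lorentzian linewidth from the TTB singlet: solve the
  # area/height ratio under the same window-and-baseline model used for
  # every other window (the ratio is independent of the line's amplitude).
  d_lo <- pr$center_ppm - pr$window_low
  d_hi <- pr$window_high - pr$center_ppm
  ratio_model <- function(w) {
    sig <- line_window_signal(pr$window_low, pr$window_high, pr$center_ppm,
                              w, baseline)
    hgt <- lorentz_pdf(0, 0, w) -
      if (identical(baseline, "endpoints_linear")) {
        (lorentz_pdf(-d_lo, 0, w) + lorentz_pdf(d_hi, 0, w)) / 2
      } else 0
    sig / hgt
  }
  target <- i_ttb_raw / height
  fwhm_ppm <- tryCatch(
    stats::uniroot(function(w) ratio_model(w) - target,
                   lower = 1e-5, upper = min(d_lo, d_hi) * 1.5)$root,
    error = function(e) 2 * i_ttb_raw / (pi * height)
  )
  cov_ttb <- window_coverage(panel, "TTB", pr$window_low, pr$window_high,
                             fwhm_ppm, sf, baseline)
  i_ttb <- i_ttb_raw / cov_ttb
  area_per_proton <- i_ttb / pr$n_protons
  # Analytic leakage of all TTB resonances into an arbitrary window.
  ttb_res <- ttb$resonances
  ttb_lines <- purrr::map_dfr(seq_len(nrow(ttb_res)), function(k) {
    ln <- resonance_lines(ttb_res$center_ppm[k], ttb_res$multiplicity[k],
                          ttb_res$j_hz[[k]], ttb_res$width_ppm[k], sf)
    ln$area <- area_per_proton * ttb_res$n_protons[k] * ln$weight
    ln
  })
  ttb_leak <- function(low, high) {
    sum(ttb_lines$area *
          line_window_signal(low, high, ttb_lines$ppm, fwhm_ppm, baseline))
  }
  list(spec = spec, panel = panel, sf = sf, sf_defaulted = sf_defaulted,
       noise = noise, baseline = baseline, i_ttb = i_ttb,
       i_ttb_raw = i_ttb_raw, fwhm_ppm = fwhm_ppm, cov_ttb = cov_ttb,
       area_per_proton = area_per_proton, ttb_leak = ttb_leak,
       is_mass_mg = is_mass_mg, ttb_mw = ttb$molar_mass,
       ttb_n = pr$n_protons)
}

# TTB-tail-corrected raw integral of one window.
window_integral <- function(ctx, low, high) {
  raw <- integrate_region(ctx$spec, c(low, high), baseline = ctx$baseline,
                          min_points = 8)
  leak <- ctx$ttb_leak(low, high)
  list(raw = raw, ttb_leak = leak, value = raw - leak)
}

# Solve the annotated-overlap cluster: distribute the measured window
# integrals of a set of mutually overlapping primary resonances into
# per-compound total areas, using the analytic fraction of each compound's
# multiplet falling in each window.  This is deterministic linear algebra on
# region integrals (the generalisation of the printed 50% PEG rule), not
# line-shape fitting: the only spectrum-derived parameter is the TTB
# linewidth.
unmix_cluster <- function(ctx, abbrevs, integrals) {
  panel <- ctx$panel
  k <- length(abbrevs)
  M <- matrix(0, k, k)
  for (j in seq_len(k)) {
    prj <- primary_resonance(panel, abbrevs[j])
    for (i in seq_len(k)) {
      M[j, i] <- window_coverage(panel, abbrevs[i], prj$window_low,
                                 prj$window_high, ctx$fwhm_ppm, ctx$sf,
                                 ctx$baseline)
    }
  }
  x <- as.numeric(solve(M, integrals))
  names(x) <- abbrevs
  x
}

mass_from_area <- function(ctx, abbrev, area) {
  pr <- primary_resonance(ctx$panel, abbrev)
  cmp <- get_compound(ctx$panel, abbrev)
  mass_from_integral(area, ctx$i_ttb, pr$n_protons, ctx$ttb_n,
                     cmp$molar_mass, ctx$ttb_mw, ctx$is_mass_mg)
}

# ---------------------------------------------------------------------------

#' Detect phenol interference in the G2 region
#'
#' Phenol's ortho/para protons resonate across 6.77-6.85 ppm, on top of the
#' PG and PGOH G2 quantification windows; high phenol content precludes use
#' of the G2 resonances.  Phenol is detected from its separate meta-proton
#' window (7.14-7.22 ppm): interference is declared when the baseline-
#' corrected peak height there exceeds `snr_threshold` times the noise
#' level estimated from a signal-free region.
#'
#' @param spec a calibrated `qnmr_spectrum`
#' @param panel a `qnmr_panel`
#' @param snr_threshold detection threshold (peak height over noise)
#' @param noise_region signal-free region for the noise estimate (ppm)
#' @return a list with elements `detected` (logical), `signal`, `noise`,
#'   `snr` and `window`
#' @export
detect_phenol_interference <- function(spec, panel = default_panel(),
                                       snr_threshold = 10,
                                       noise_region = c(9.5, 10)) {
  pr <- primary_resonance(panel, "PHENOL")
  noise <- spectrum_noise(spec, noise_region)
  idx <- which(spec$ppm >= pr$window_low & spec$ppm <= pr$window_high)
  if (length(idx) < 3) stop("phenol window spans too few points", call. = FALSE)
  x <- spec$ppm[idx]; y <- spec$intensity[idx]
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(y)
  chord <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  signal <- max(y - chord)
  snr <- if (noise > 0) signal / noise else Inf
  list(detected = isTRUE(signal > snr_threshold * noise),
       signal = signal, noise = noise, snr = snr,
       window = c(pr$window_low, pr$window_high))
}

ALIPHATIC_WINDOWS <- tibble::tribble(
  ~window_id,            ~side_chain,     ~low,  ~high, ~n_protons,
  "ethyl_beta",          "ethyl",         1.130, 1.200, 3,
  "propyl_gamma",        "propyl",        0.860, 0.930, 3,
  "propyl_beta",         "propyl",        1.530, 1.640, 2,
  "hydroxypropyl_gamma", "hydroxypropyl", 3.450, 3.580, 2,
  "alkene_alpha",        "alkene",        6.280, 6.350, 1,
  "alkene_beta",         "alkene",        6.060, 6.150, 1
)

#' Side-chain profile from the aliphatic and alkene regions
#'
#' The aliphatic region discriminates side chains (ethyl, propyl,
#' 3-hydroxypropyl, propenyl) rather than S/G ring type, and so corroborates
#' the selectivity read from the aromatic region.  Integrates the six
#' diagnostic windows, normalises each per proton against the internal
#' standard's per-proton integral, and flags which side chains are present.
#'
#' @param spec a calibrated `qnmr_spectrum`
#' @param panel a `qnmr_panel`
#' @param threshold presence threshold on the per-proton molar ratio to TTB
#' @param baseline baseline mode passed to [integrate_region()]
#' @return a tibble with one row per diagnostic window: `window_id`,
#'   `side_chain`, window bounds, `integral` (TTB tails subtracted),
#'   `per_proton_ratio` (molar ratio to TTB) and `present`
#' @export
aliphatic_crosscheck <- function(spec, panel = default_panel(),
                                 threshold = 0.05,
                                 baseline = "endpoints_linear") {
  ctx <- quant_context(spec, panel, baseline = baseline)
  profile_from_ctx(ctx, threshold)
}

profile_from_ctx <- function(ctx, threshold = 0.05) {
  w <- ALIPHATIC_WINDOWS
  vals <- purrr::map(seq_len(nrow(w)), function(i) {
    window_integral(ctx, w$low[i], w$high[i])
  })
  w$integral <- vapply(vals, function(v) v$value, numeric(1))
  w$per_proton_ratio <- (w$integral / w$n_protons) / ctx$area_per_proton
  w$present <- w$per_proton_ratio > threshold
  w
}

#' Recover G-type monomers from the aliphatic region
#'
#' When the G2 region is unusable (phenol interference, or EG/PGOH overlap
#' flagged by an ethyl side-chain signal), the side-chain windows give the
#' total molar amount per side chain; subtracting the S-type contribution
#' known from the clean S2/6 singlets leaves the G-type amount:
#' PG from propyl-gamma minus PS, PGOH from the clean hydroxypropyl-gamma
#' window (3.45-3.58 ppm, the only hydroxypropyl window free of overlap)
#' minus PSOH, and EG from ethyl-beta minus ES.
#'
#' @param spec a calibrated `qnmr_spectrum`
#' @param s_results a quantification table containing rows for PS, PSOH and
#'   (optionally) ES with `compound` and `mass_mg` columns
#' @param prep a `qnmr_prep`
#' @param panel a `qnmr_panel`
#' @param baseline baseline mode
#' @param neg_tol negative-inference tolerance: an inferred G amount below
#'   `-neg_tol` times the side-chain total is flagged unreliable
#' @return a tibble with rows for PG, PGOH and EG (method
#'   `"aliphatic_fallback"`)
#' @export
quantify_g_from_aliphatic <- function(spec, s_results, prep,
                                      panel = default_panel(),
                                      baseline = "endpoints_linear",
                                      neg_tol = 0.1) {
  ctx <- quant_context(spec, panel, baseline = baseline,
                       is_mass_mg = prep$is_mass_mg)
  fallback_from_ctx(ctx, s_results, prep, neg_tol)
}

fallback_from_ctx <- function(ctx, s_results, prep, neg_tol = 0.1) {
  panel <- ctx$panel
  mol_ttb <- ctx$is_mass_mg / ctx$ttb_mw
  s_mol <- function(ab) {
    i <- match(ab, s_results$compound)
    if (is.na(i) || is.na(s_results$mass_mg[i])) return(NA_real_)
    s_results$mass_mg[i] / get_compound(panel, ab)$molar_mass
  }
  # window label in the panel -> (S compound, G compound)
  chains <- list(
    PG   = list(window = "propyl_gamma",        s = "PS",   label = "propyl-gamma"),
    PGOH = list(window = "hydroxypropyl_gamma", s = "PSOH", label = "hydroxypropyl-gamma"),
    EG   = list(window = "ethyl_beta",          s = "ES",   label = "ethyl-beta")
  )
  purrr::map_dfr(names(chains), function(g_ab) {
    ch <- chains[[g_ab]]
    w <- ALIPHATIC_WINDOWS[ALIPHATIC_WINDOWS$window_id == ch$window, ]
    # Coverage of the shared side-chain multiplet in its window (same line
    # model for the S and G partner; use the G compound's resonance row).
    rr <- panel$resonances
    row <- rr[rr$abbrev == g_ab & rr$label == ch$label, ]
    ln <- resonance_lines(row$center_ppm, row$multiplicity, row$j_hz[[1]],
                          row$width_ppm, ctx$sf)
    cov <- sum(ln$weight *
                 line_window_signal(w$low, w$high, ln$ppm, ctx$fwhm_ppm,
                                    ctx$baseline))
    wi <- window_integral(ctx, w$low, w$high)
    total_area <- wi$value / cov
    total_mol <- (total_area / w$n_protons) / ctx$area_per_proton * mol_ttb
    sm <- s_mol(ch$s)
    flags <- c("aliphatic_fallback")
    if (is.na(sm)) {
      sm <- 0
      flags <- c(flags, paste0(ch$s, "_unavailable"))
    }
    g_mol <- total_mol - sm
    reliable <- TRUE
    if (g_mol < -neg_tol * max(total_mol, .Machine$double.eps)) {
      reliable <- FALSE
      flags <- c(flags, "negative_inference_floored")
    }
    g_mol <- max(g_mol, 0)
    mw <- get_compound(panel, g_ab)$molar_mass
    mass <- g_mol * mw
    tibble::tibble(
      compound = g_ab,
      cls = get_compound(panel, g_ab)$cls,
      method = "aliphatic_fallback",
      raw_integral = wi$raw,
      corrected_integral = total_area,
      mass_mg = mass,
      conc_mg_per_ml = mass / prep$aliquot_ml,
      yield_wt_pct = yield_from_mass(mass, prep),
      reliable = reliable,
      flags = paste(flags, collapse = ";")
    )
  })
}

# ---------------------------------------------------------------------------

# Local-maximum check for the narrow ES window: ES is reported only when its
# window shows a peak distinct from the adjacent PS/PSOH band.
es_distinguishable <- function(ctx, tol_ppm = 0.005, snr_min = 3) {
  pr <- primary_resonance(ctx$panel, "ES")
  spec <- ctx$spec
  idx <- which(spec$ppm >= pr$window_low & spec$ppm <= pr$window_high)
  if (length(idx) < 5) return(FALSE)
  x <- spec$ppm[idx]; y <- spec$intensity[idx]
  o <- order(x); x <- x[o]; y <- y[o]
  k <- which.max(y)
  n <- length(y)
  interior <- x[k] > x[1] + tol_ppm && x[k] < x[n] - tol_ppm
  height <- y[k] - min(y[1], y[n])
  interior && y[k] > y[1] && y[k] > y[n] && height > snr_min * ctx$noise
}

#' Quantify an RCF-oil spectrum
#'
#' The full internal-standard quantification pipeline:
#' \enumerate{
#'   \item calibrate the ppm axis on the TTB aromatic singlet (optional);
#'   \item integrate the TTB window, estimate the effective linewidth from
#'     its area/height ratio, and subtract the analytic TTB tail from every
#'     other window;
#'   \item integrate every quantification window with a local linear
#'     baseline;
#'   \item subtract 50% of the PEG G2 integral from the PG G2 integral
#'     (PEG G5 overlap), flooring at zero;
#'   \item resolve the annotated overlapping window clusters
#'     (PS/PSOH/ES, PG/PGOH, pHBA/MP) by deterministic linear unmixing and
#'     correct all windows for finite-window coverage;
#'   \item check that ES shows a distinct local maximum, otherwise flag it
#'     "not distinguishable";
#'   \item detect phenol interference; if present, flag every G2-window
#'     quantification unreliable; an ethyl side-chain signal likewise flags
#'     PGOH (EG overlap);
#'   \item when the G2 route is flagged, re-quantify PG/PGOH/EG from the
#'     aliphatic side-chain windows ([quantify_g_from_aliphatic()]);
#'   \item estimate EG from ES and the PS/PG ratio when no direct or
#'     fallback route exists;
#'   \item convert areas to masses against the weighed TTB and to wt%
#'     yields via the sample preparation.
#' }
#' Every correction is logged in the `corrections` attribute and in the
#' per-compound `flags`.
#'
#' @param spec a `qnmr_spectrum`
#' @param prep a `qnmr_prep`
#' @param panel a `qnmr_panel`
#' @param calibrate logical: reference the axis to the TTB singlet first
#' @param baseline baseline mode for all integrations
#' @param noise_region signal-free region (ppm) for noise estimation
#' @param phenol_snr_threshold threshold for [detect_phenol_interference()]
#' @param aliphatic_threshold presence threshold for [aliphatic_crosscheck()]
#' @return a tibble of class `qnmr_result`, one row per compound, with
#'   columns `compound`, `cls`, `method`, `raw_integral`,
#'   `corrected_integral`, `mass_mg`, `conc_mg_per_ml`, `yield_wt_pct`,
#'   `reliable` and `flags`; attributes `prep`, `corrections`, `phenol`,
#'   `aliphatic`, `linewidth_hz`, `noise` and `hb_total_yield` (the
#'   pHBA + MP sum, the convention for the shared hydroxybenzoate windows)
#' @export
quantify <- function(spec, prep = sample_prep(), panel = default_panel(),
                     calibrate = TRUE, baseline = "endpoints_linear",
                     noise_region = c(9.5, 10), phenol_snr_threshold = 10,
                     aliphatic_threshold = 0.05) {
  stopifnot(inherits(spec, "qnmr_spectrum"), inherits(prep, "qnmr_prep"))
  if (calibrate) {
    ttb_pr <- primary_resonance(panel, "TTB")
    spec <- calibrate_ppm(spec, ttb_pr$center_ppm,
                          c(ttb_pr$center_ppm - 0.08, ttb_pr$center_ppm + 0.08),
                          noise_region = noise_region)
  }
  ctx <- quant_context(spec, panel, baseline = baseline,
                       noise_region = noise_region,
                       is_mass_mg = prep$is_mass_mg)
  corrections <- list()
  log_corr <- function(compound, rule, amount) {
    corrections[[length(corrections) + 1]] <<-
      tibble::tibble(compound = compound, rule = rule, amount = amount)
  }

  direct <- setdiff(panel$compounds$abbrev, c("TTB", "EG"))
  raws <- purrr::map(direct, function(ab) {
    pr <- primary_resonance(panel, ab)
    wi <- window_integral(ctx, pr$window_low, pr$window_high)
    if (abs(wi$ttb_leak) > 0) log_corr(ab, "ttb_tail_subtraction", -wi$ttb_leak)
    wi
  })
  names(raws) <- direct
  ivals <- vapply(raws, function(v) v$value, numeric(1))

  # PEG is integrated before PG so the subtraction uses the same spectrum's PEG integral.
  pg_corr <- correct_pg_integral(max(ivals[["PG"]], 0), max(ivals[["PEG"]], 0))
  log_corr("PG", "peg_g2_subtraction", -0.5 * max(ivals[["PEG"]], 0))
  pg_floored <- isTRUE(attr(pg_corr, "floored"))
  ivals[["PG"]] <- as.numeric(pg_corr)

  es_ok <- es_distinguishable(ctx)

  # Overlap clusters resolved jointly; isolated compounds are a cluster of
  # one (pure coverage correction).
  clusters <- list(
    s_band = if (es_ok) c("PS", "PSOH", "ES") else c("PS", "PSOH"),
    g_band = c("PG", "PGOH"),
    hb_band = c("PHBA", "MP"),
    pes = "PES", peg = "PEG", phenol = "PHENOL"
  )
  areas <- numeric(0)
  floored_unmix <- character(0)
  for (cl in clusters) {
    x <- unmix_cluster(ctx, cl, ivals[cl])
    for (ab in cl) {
      log_corr(ab, "window_coverage_and_overlap_unmix", x[[ab]] - ivals[[ab]])
      if (x[[ab]] < 0) {
        floored_unmix <- c(floored_unmix, ab)
        x[[ab]] <- 0
      }
      areas[[ab]] <- x[[ab]]
    }
  }

  phenol_chk <- detect_phenol_interference(ctx$spec, panel,
                                           snr_threshold = phenol_snr_threshold,
                                           noise_region = noise_region)
  profile <- profile_from_ctx(ctx, aliphatic_threshold)
  ethyl_present <- any(profile$present[profile$side_chain == "ethyl"])

  res <- purrr::map_dfr(names(areas), function(ab) {
    area <- areas[[ab]]
    mass <- mass_from_area(ctx, ab, area)
    flags <- character(0)
    if (ab == "PG") {
      flags <- c(flags, "peg_g2_subtraction")
      if (pg_floored) flags <- c(flags, "pg_correction_floored")
    }
    if (ab %in% floored_unmix) flags <- c(flags, "negative_area_floored")
    if (ab %in% c("PHBA", "MP")) flags <- c(flags, "shared_printed_window")
    tibble::tibble(
      compound = ab, cls = get_compound(panel, ab)$cls, method = "direct",
      raw_integral = raws[[ab]]$raw, corrected_integral = area,
      mass_mg = mass, conc_mg_per_ml = mass / prep$aliquot_ml,
      yield_wt_pct = yield_from_mass(mass, prep),
      reliable = TRUE, flags = paste(flags, collapse = ";")
    )
  })

  if (!es_ok) {
    es_row <- tibble::tibble(
      compound = "ES", cls = "S", method = "direct",
      raw_integral = raws[["ES"]]$raw, corrected_integral = NA_real_,
      mass_mg = NA_real_, conc_mg_per_ml = NA_real_,
      yield_wt_pct = NA_real_, reliable = FALSE,
      flags = "not_distinguishable_from_s_band"
    )
    res <- dplyr::bind_rows(res, es_row)
  }

  # Interference gating of the G2 region.
  g2_gated <- character(0)
  if (phenol_chk$detected) g2_gated <- c("PG", "PGOH")
  if (ethyl_present) g2_gated <- union(g2_gated, "PGOH")
  gate_reason <- paste(
    c(if (phenol_chk$detected) "phenol_interference",
      if (ethyl_present) "eg_overlap_ethyl_detected"),
    collapse = ";"
  )
  add_flag <- function(flags, new) {
    paste(c(setdiff(strsplit(flags, ";")[[1]], ""), new), collapse = ";")
  }
  for (ab in g2_gated) {
    i <- match(ab, res$compound)
    res$reliable[i] <- FALSE
    res$flags[i] <- add_flag(res$flags[i],
                             paste0("g2_unreliable(", gate_reason, ")"))
  }

  eg_row <- NULL
  if (length(g2_gated)) {
    fb <- fallback_from_ctx(ctx, res, prep)
    for (ab in intersect(g2_gated, fb$compound)) {
      i <- match(ab, res$compound)
      j <- match(ab, fb$compound)
      old_flags <- res$flags[i]
      res[i, ] <- fb[j, ]
      res$flags[i] <- add_flag(old_flags, strsplit(fb$flags[j], ";")[[1]])
      log_corr(ab, "aliphatic_fallback", NA_real_)
    }
    if (ethyl_present) eg_row <- fb[fb$compound == "EG", ]
  }
  if (is.null(eg_row)) {
    # EG by the ES x (PG/PS) estimate when possible.
    ps_y <- res$yield_wt_pct[match("PS", res$compound)]
    pg_y <- res$yield_wt_pct[match("PG", res$compound)]
    es_y <- res$yield_wt_pct[match("ES", res$compound)]
    if (!is.na(es_y) && !is.na(ps_y) && ps_y > 0 && !is.na(pg_y)) {
      eg_y <- estimate_eg_yield(es_y, ps_y, pg_y)
      eg_mass <- eg_y / 100 * prep$basis_mass_mg *
        prep$aliquot_ml / prep$total_liquor_ml
      eg_row <- tibble::tibble(
        compound = "EG", cls = "G", method = "estimated_from_es",
        raw_integral = NA_real_, corrected_integral = NA_real_,
        mass_mg = eg_mass, conc_mg_per_ml = eg_mass / prep$aliquot_ml,
        yield_wt_pct = eg_y, reliable = TRUE,
        flags = "estimate;never_directly_integrated"
      )
    } else {
      eg_row <- tibble::tibble(
        compound = "EG", cls = "G", method = "not_quantified",
        raw_integral = NA_real_, corrected_integral = NA_real_,
        mass_mg = NA_real_, conc_mg_per_ml = NA_real_,
        yield_wt_pct = NA_real_, reliable = FALSE,
        flags = "not_quantified(no_es_or_ps_reference)"
      )
    }
  }
  res <- dplyr::bind_rows(res, eg_row)
  ord <- c("PS", "PSOH", "PG", "PGOH", "ES", "EG", "PES", "PEG",
           "PHBA", "MP", "PHENOL")
  res <- res[order(match(res$compound, ord)), ]
  res$flags[res$flags == ""] <- NA_character_

  hb <- res$yield_wt_pct[res$compound %in% c("PHBA", "MP")]
  class(res) <- c("qnmr_result", class(res))
  attr(res, "prep") <- prep
  attr(res, "corrections") <- dplyr::bind_rows(corrections)
  attr(res, "phenol") <- phenol_chk
  attr(res, "aliphatic") <- profile
  attr(res, "linewidth_hz") <- ctx$fwhm_ppm * ctx$sf
  attr(res, "noise") <- ctx$noise
  attr(res, "hb_total_yield") <- sum(hb, na.rm = TRUE)
  if (ctx$sf_defaulted) {
    attr(res, "sf_defaulted") <- TRUE
  }
  res
}

#' @export
print.qnmr_result <- function(x, ...) {
  cat(sprintf("<qnmr_result> %d compounds; linewidth %.2f Hz; pHBA+MP sum %.2f wt%%\n",
              nrow(x), attr(x, "linewidth_hz"), attr(x, "hb_total_yield")))
  if (isTRUE(attr(x, "phenol")$detected)) {
    cat("  phenol interference detected: G2-region quantifications gated\n")
  }
  NextMethod()
}
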