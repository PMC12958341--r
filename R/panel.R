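#' Compound and resonance panel for RCF-oil qNMR
#'
#' The panel encodes every compound the quantification method knows about:
#' the four primary lignin monomers (PS, PSOH, PG, PGOH), the minor 4-ethyl
#' and 4-propenyl monomers (ES, EG, PES, PEG), the poplar-specific
#' hydroxybenzoates (pHBA, methyl paraben), phenol, and the internal standard
#' 1,3,5-tri-tert-butylbenzene (TTB).  Each compound carries a molecular
#' formula (molar masses are always computed from the formula, never stored
#' as magic numbers), an S/G/H/phenol/internal-standard class, and a list of
#' assigned resonances with chemical shift, multiplicity, couplings, proton
#' count, integration window and role.
#'
#' @name panel
NULL

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Molar mass from a molecular formula
#'
#' @param formula molecular formula string, e.g. `"C11H16O3"`
#' @return molar mass in g/mol
#' @examples
#' formula_mass("C18H30") # TTB
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)(\\d*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!nzchar(f) || sum(nchar(toks)) != nchar(f)) {
      stop("cannot parse molecular formula: ", f, call. = FALSE)
    }
    total <- 0
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      n <- gsub("[^0-9]", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (!el %in% names(ATOMIC_MASS)) {
        stop("unknown element '", el, "' in formula ", f, call. = FALSE)
      }
      total <- total + ATOMIC_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

new_panel <- function(compounds, resonances, overlaps, version = "1.0") {
  structure(
    list(
      compounds = compounds,
      resonances = resonances,
      overlaps = overlaps,
      version = version
    ),
    class = "qnmr_panel"
  )
}

# One resonance row; j is a numeric vector (empty for singlets).
res_row <- function(abbrev, label, center, mult, j, n_h, low, high, role,
                    primary = FALSE, width = 0.04) {
  tibble::tibble(
    abbrev = abbrev, label = label, center_ppm = center,
    multiplicity = mult, j_hz = list(j), n_protons = n_h,
    window_low = low, window_high = high, width_ppm = width,
    role = role, primary = primary
  )
}

#' Default 12-compound poplar panel
#'
#' Returns the built-in panel covering typical poplar RCF oils.  Chemical
#' shift windows follow the published assignments for the aromatic
#' quantification resonances (S2/6 singlets of the syringyl compounds, G2 of
#' the guaiacyl compounds, H2/6 of the hydroxybenzoates) and for the
#' diagnostic aliphatic side-chain and alkene windows.  Where only a shared
#' band is printed (the PS/PSOH/ES S2/6 band at 6.46-6.50 ppm, the PG/PGOH
#' G2 band at 6.77-6.82 ppm, the pHBA/MP H2/6 band at 7.87-7.93 ppm) the
#' band is split into disjoint adjacent sub-windows, one per compound, so
#' that no spectral point is ever counted twice; every default is
#' user-overridable via [read_panel()].  Known overlaps (PEG G5 under the PG
#' G2 window, EG G2 under the PGOH G2 window, phenol across the whole G2
#' region, ES adjacent to the PS/PSOH band, pHBA/MP sharing printed windows,
#' and the aliphatic alpha/beta collisions) are recorded as explicit
#' annotations queryable with [overlap_pairs()].
#'
#' @return an object of class `qnmr_panel`
#' @examples
#' p <- default_panel()
#' get_compound(p, "PES")
#' @export
default_panel <- function() {
  compounds <- tibble::tribble(
    ~abbrev,  ~name,                              ~formula,   ~cls,
    "PS",     "4-propylsyringol",                 "C11H16O3", "S",
    "PSOH",   "4-(3-hydroxypropyl)syringol",      "C11H16O4", "S",
    "PG",     "4-propylguaiacol",                 "C10H14O2", "G",
    "PGOH",   "4-(3-hydroxypropyl)guaiacol",      "C10H14O3", "G",
    "ES",     "4-ethylsyringol",                  "C10H14O3", "S",
    "EG",     "4-ethylguaiacol",                  "C9H12O2",  "G",
    "PES",    "4-propenylsyringol",               "C11H14O3", "S",
    "PEG",    "4-propenylguaiacol (isoeugenol)",  "C10H12O2", "G",
    "PHBA",   "p-hydroxybenzoic acid",            "C7H6O3",   "H",
    "MP",     "methyl paraben",                   "C8H8O3",   "H",
    "PHENOL", "phenol",                           "C6H6O",    "phenol",
    "TTB",    "1,3,5-tri-tert-butylbenzene",      "C18H30",   "internal_standard"
  )
  compounds$molar_mass <- formula_mass(compounds$formula)

  no_j <- numeric()
  r <- dplyr::bind_rows(
    # PS ------------------------------------------------------------------
    res_row("PS", "S2/6", 6.463, "singlet", no_j, 2, 6.456, 6.470,
            "quantification", primary = TRUE),
    res_row("PS", "propyl-gamma", 0.895, "multiplet", no_j, 3, 0.860, 0.930,
            "diagnostic", width = 0.030),
    res_row("PS", "propyl-beta", 1.585, "multiplet", no_j, 2, 1.530, 1.640,
            "diagnostic", width = 0.040),
    res_row("PS", "propyl-alpha", 2.470, "multiplet", no_j, 2, 2.420, 2.520,
            "diagnostic", width = 0.030),
    res_row("PS", "OMe", 3.795, "singlet", no_j, 6, 3.765, 3.825, "diagnostic"),
    # PSOH ----------------------------------------------------------------
    res_row("PSOH", "S2/6", 6.477, "singlet", no_j, 2, 6.470, 6.484,
            "quantification", primary = TRUE),
    res_row("PSOH", "hydroxypropyl-gamma", 3.515, "multiplet", no_j, 2,
            3.450, 3.580, "diagnostic", width = 0.030),
    res_row("PSOH", "hydroxypropyl-beta", 1.780, "multiplet", no_j, 2,
            1.720, 1.840, "diagnostic", width = 0.040),
    res_row("PSOH", "hydroxypropyl-alpha", 2.580, "multiplet", no_j, 2,
            2.530, 2.630, "interference", width = 0.030),
    res_row("PSOH", "OMe", 3.800, "singlet", no_j, 6, 3.770, 3.830, "diagnostic"),
    # PG ------------------------------------------------------------------
    res_row("PG", "G2", 6.785, "doublet", 2.0, 1, 6.770, 6.800,
            "quantification", primary = TRUE),
    res_row("PG", "G5", 6.865, "doublet", 8.1, 1, 6.835, 6.895, "diagnostic"),
    res_row("PG", "G6", 6.730, "dd", c(8.1, 2.0), 1, 6.700, 6.760, "diagnostic"),
    res_row("PG", "propyl-gamma", 0.895, "multiplet", no_j, 3, 0.860, 0.930,
            "diagnostic", width = 0.030),
    res_row("PG", "propyl-beta", 1.585, "multiplet", no_j, 2, 1.530, 1.640,
            "diagnostic", width = 0.040),
    res_row("PG", "propyl-alpha", 2.470, "multiplet", no_j, 2, 2.420, 2.520,
            "diagnostic", width = 0.030),
    res_row("PG", "OMe", 3.825, "singlet", no_j, 3, 3.795, 3.855, "diagnostic"),
    # PGOH ----------------------------------------------------------------
    res_row("PGOH", "G2", 6.810, "doublet", 2.0, 1, 6.800, 6.820,
            "quantification", primary = TRUE),
    res_row("PGOH", "G5", 6.872, "doublet", 8.1, 1, 6.842, 6.902, "diagnostic"),
    res_row("PGOH", "G6", 6.735, "dd", c(8.1, 2.0), 1, 6.705, 6.765, "diagnostic"),
    res_row("PGOH", "hydroxypropyl-gamma", 3.515, "multiplet", no_j, 2,
            3.450, 3.580, "diagnostic", width = 0.030),
    res_row("PGOH", "hydroxypropyl-beta", 1.780, "multiplet", no_j, 2,
            1.720, 1.840, "diagnostic", width = 0.040),
    res_row("PGOH", "hydroxypropyl-alpha", 2.580, "multiplet", no_j, 2,
            2.530, 2.630, "interference", width = 0.030),
    res_row("PGOH", "OMe", 3.830, "singlet", no_j, 3, 3.800, 3.860, "diagnostic"),
    # ES ------------------------------------------------------------------
    res_row("ES", "S2/6", 6.491, "singlet", no_j, 2, 6.484, 6.498,
            "quantification", primary = TRUE),
    res_row("ES", "ethyl-beta", 1.165, "multiplet", no_j, 3, 1.130, 1.200,
            "diagnostic", width = 0.025),
    res_row("ES", "ethyl-alpha", 2.545, "multiplet", no_j, 2, 2.495, 2.595,
            "interference", width = 0.030),
    res_row("ES", "OMe", 3.790, "singlet", no_j, 6, 3.760, 3.820, "diagnostic"),
    # EG ------------------------------------------------------------------
    # EG's G2 lies under the PGOH G2 window (annotated overlap); the
    # pipeline never integrates it directly -- EG is estimated from ES and
    # the PS/PG ratio, or recovered from the ethyl-beta window.
    res_row("EG", "G2", 6.807, "doublet", 2.0, 1, 6.800, 6.816,
            "quantification", primary = TRUE),
    res_row("EG", "G5", 6.855, "doublet", 8.1, 1, 6.825, 6.885, "diagnostic"),
    res_row("EG", "G6", 6.720, "dd", c(8.1, 2.0), 1, 6.690, 6.750, "diagnostic"),
    res_row("EG", "ethyl-beta", 1.165, "multiplet", no_j, 3, 1.130, 1.200,
            "diagnostic", width = 0.025),
    res_row("EG", "ethyl-alpha", 2.545, "multiplet", no_j, 2, 2.495, 2.595,
            "interference", width = 0.030),
    res_row("EG", "OMe", 3.820, "singlet", no_j, 3, 3.790, 3.850, "diagnostic"),
    # PES -----------------------------------------------------------------
    res_row("PES", "S2/6", 6.660, "singlet", no_j, 2, 6.650, 6.670,
            "quantification", primary = TRUE),
    res_row("PES", "alkene-alpha", 6.315, "doublet", 15.8, 1, 6.280, 6.350,
            "diagnostic"),
    res_row("PES", "alkene-beta", 6.105, "multiplet", no_j, 1, 6.060, 6.150,
            "diagnostic", width = 0.035),
    res_row("PES", "propenyl-gamma", 1.845, "doublet", 6.5, 3, 1.805, 1.885,
            "diagnostic"),
    res_row("PES", "OMe", 3.805, "singlet", no_j, 6, 3.775, 3.835, "diagnostic"),
    # PEG -----------------------------------------------------------------
    # The PEG G5 dd is centred on the lower edge of the PG G2 window, so
    # about half of its area falls inside that window; this is the physical
    # basis of the 50% PEG-G2 subtraction rule, see correct_pg_integral().
    res_row("PEG", "G2", 6.990, "doublet", 2.0, 1, 6.960, 7.020,
            "quantification", primary = TRUE),
    res_row("PEG", "G5", 6.770, "dd", c(8.1, 1.6), 1, 6.740, 6.800,
            "interference"),
    res_row("PEG", "G6", 6.850, "doublet", 8.1, 1, 6.820, 6.880, "diagnostic"),
    res_row("PEG", "alkene-alpha", 6.315, "doublet", 15.8, 1, 6.280, 6.350,
            "diagnostic"),
    res_row("PEG", "alkene-beta", 6.105, "multiplet", no_j, 1, 6.060, 6.150,
            "diagnostic", width = 0.035),
    res_row("PEG", "propenyl-gamma", 1.845, "doublet", 6.5, 3, 1.805, 1.885,
            "diagnostic"),
    res_row("PEG", "OMe", 3.835, "singlet", no_j, 3, 3.805, 3.865, "diagnostic"),
    # PHBA ----------------------------------------------------------------
    res_row("PHBA", "H2/6", 7.885, "doublet", 8.7, 2, 7.870, 7.900,
            "quantification", primary = TRUE),
    res_row("PHBA", "H3/5", 6.905, "doublet", 8.7, 2, 6.890, 6.920, "diagnostic"),
    # MP ------------------------------------------------------------------
    res_row("MP", "H2/6", 7.915, "doublet", 8.7, 2, 7.900, 7.930,
            "quantification", primary = TRUE),
    res_row("MP", "H3/5", 6.925, "doublet", 8.7, 2, 6.910, 6.940, "diagnostic"),
    res_row("MP", "OMe", 3.870, "singlet", no_j, 3, 3.840, 3.900, "diagnostic"),
    # PHENOL --------------------------------------------------------------
    res_row("PHENOL", "H3/5", 7.180, "multiplet", no_j, 2, 7.140, 7.220,
            "quantification", primary = TRUE, width = 0.050),
    res_row("PHENOL", "H2/6+H4", 6.810, "multiplet", no_j, 3, 6.770, 6.850,
            "interference", width = 0.060),
    # TTB -----------------------------------------------------------------
    # Aromatic shift set at 7.30 ppm by convention (user-overridable).
    res_row("TTB", "aromatic", 7.300, "singlet", no_j, 3, 7.270, 7.330,
            "quantification", primary = TRUE),
    res_row("TTB", "tert-butyl", 1.340, "singlet", no_j, 27, 1.310, 1.370,
            "diagnostic")
  )

  overlaps <- tibble::tribble(
    ~a,      ~b,       ~note,
    "PG",    "PEG",    "PEG G5 dd partially overlaps the PG G2 window; corrected by subtracting 50% of the PEG G2 integral",
    "PGOH",  "EG",     "EG G2 (6.80 ppm) partially overlaps PGOH G2; EG is estimated from ES and the PS/PG ratio or from the ethyl-beta window",
    "PG",    "PHENOL", "phenol ortho/para multiplet (6.77-6.85 ppm) spans the G2 quantification region",
    "PGOH",  "PHENOL", "phenol ortho/para multiplet (6.77-6.85 ppm) spans the G2 quantification region",
    "ES",    "PS",     "ES S2/6 (6.49 ppm) is adjacent to the PS/PSOH S2/6 band (6.46-6.50 ppm)",
    "ES",    "PSOH",   "ES S2/6 (6.49 ppm) is adjacent to the PS/PSOH S2/6 band (6.46-6.50 ppm)",
    "PS",    "PSOH",   "S2/6 singlets share the printed 6.46-6.50 ppm band; split into adjacent sub-windows",
    "PG",    "PGOH",   "G2 resonances share the printed 6.77-6.82 ppm band; split into adjacent sub-windows",
    "PHBA",  "MP",     "H2/6 and H3/5 printed as shared ranges; reported individually and as a sum",
    "PSOH",  "ES",     "hydroxypropyl-alpha overlaps ethyl-alpha",
    "PGOH",  "EG",     "hydroxypropyl-alpha overlaps ethyl-alpha",
    "PSOH",  "PES",    "hydroxypropyl-beta overlaps propenyl-gamma",
    "PGOH",  "PEG",    "hydroxypropyl-beta overlaps propenyl-gamma"
  )

  p <- new_panel(compounds, r, overlaps, version = "1.0")
  validate_panel(p)
  p
}

#' Validate a panel against its structural invariants
#'
#' Checks abbreviation uniqueness, window orientation, that quantification
#' resonance centres lie inside their windows, proton counts, that singlets
#' carry no couplings, molar-mass/formula consistency, that every compound
#' designates exactly one primary quantification resonance, and that
#' overlapping primary quantification windows of distinct compounds are
#' covered by an overlap annotation.
#'
#' @param panel a `qnmr_panel`
#' @return the panel, invisibly; errors describe the first violated invariant
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "qnmr_panel"))
  cmp <- panel$compounds
  res <- panel$resonances
  if (anyDuplicated(cmp$abbrev)) stop("duplicate compound abbreviations", call. = FALSE)
  if (!all(res$abbrev %in% cmp$abbrev)) {
    stop("resonances refer to unknown compounds: ",
         paste(setdiff(res$abbrev, cmp$abbrev), collapse = ", "), call. = FALSE)
  }
  if (any(res$window_low >= res$window_high)) {
    stop("every window must satisfy low < high", call. = FALSE)
  }
  if (any(res$n_protons < 1)) stop("n_protons must be >= 1", call. = FALSE)
  qr <- res[res$role == "quantification", ]
  bad <- qr$center_ppm < qr$window_low | qr$center_ppm > qr$window_high
  if (any(bad)) {
    stop("quantification resonance centre outside its window: ",
         paste(qr$abbrev[bad], qr$label[bad], collapse = ", "), call. = FALSE)
  }
  single_j <- vapply(
    seq_len(nrow(res)),
    function(i) res$multiplicity[i] == "singlet" && length(res$j_hz[[i]]) > 0,
    logical(1)
  )
  if (any(single_j)) stop("singlet resonances must have no couplings", call. = FALSE)
  dm <- abs(cmp$molar_mass - formula_mass(cmp$formula))
  if (any(dm > 0.01)) {
    stop("stored molar mass inconsistent with formula for: ",
         paste(cmp$abbrev[dm > 0.01], collapse = ", "), call. = FALSE)
  }
  n_primary <- vapply(cmp$abbrev, function(a) {
    sum(res$abbrev == a & res$primary & res$role == "quantification")
  }, numeric(1))
  if (any(n_primary != 1)) {
    stop("each compound needs exactly one primary quantification resonance; offending: ",
         paste(cmp$abbrev[n_primary != 1], collapse = ", "), call. = FALSE)
  }
  # Overlapping primary windows must be annotated.
  pr <- res[res$primary & res$role == "quantification", ]
  ann <- paste(pmin(panel$overlaps$a, panel$overlaps$b),
               pmax(panel$overlaps$a, panel$overlaps$b))
  for (i in seq_len(nrow(pr))) {
    for (j in seq_len(nrow(pr))) {
      if (j <= i) next
      if (pr$window_low[i] < pr$window_high[j] &&
          pr$window_low[j] < pr$window_high[i]) {
        key <- paste(min(pr$abbrev[i], pr$abbrev[j]), max(pr$abbrev[i], pr$abbrev[j]))
        if (!key %in% ann) {
          stop("unannotated overlap between quantification windows of ",
               pr$abbrev[i], " and ", pr$abbrev[j], call. = FALSE)
        }
      }
    }
  }
  invisible(panel)
}

#' Look up one compound and its resonances
#'
#' @param panel a `qnmr_panel`
#' @param abbrev compound abbreviation, e.g. `"PS"` or `"TTB"`
#' @return a list of class `qnmr_compound` with fields `abbrev`, `name`,
#'   `formula`, `molar_mass`, `cls` and a `resonances` tibble
#' @export
get_compound <- function(panel, abbrev) {
  stopifnot(inherits(panel, "qnmr_panel"))
  i <- match(abbrev, panel$compounds$abbrev)
  if (is.na(i)) {
    stop("unknown compound '", abbrev, "'; available: ",
         paste(panel$compounds$abbrev, collapse = ", "), call. = FALSE)
  }
  row <- panel$compounds[i, ]
  structure(
    list(
      abbrev = row$abbrev, name = row$name, formula = row$formula,
      molar_mass = row$molar_mass, cls = row$cls,
      resonances = panel$resonances[panel$resonances$abbrev == abbrev, ]
    ),
    class = "qnmr_compound"
  )
}

# Primary quantification resonance row of one compound.
primary_resonance <- function(panel, abbrev) {
  r <- panel$resonances
  out <- r[r$abbrev == abbrev & r$primary & r$role == "quantification", ]
  if (nrow(out) != 1) stop("no unique primary resonance for ", abbrev, call. = FALSE)
  out
}

#' Annotated overlap pairs
#'
#' @param panel a `qnmr_panel`
#' @return a tibble with columns `a`, `b`, `note`; one row per annotated
#'   overlap between compounds
#' @export
overlap_pairs <- function(panel) {
  stopifnot(inherits(panel, "qnmr_panel"))
  panel$overlaps
}

#' @export
print.qnmr_panel <- function(x, ...) {
  cat("<qnmr_panel> version ", x$version, ": ", nrow(x$compounds),
      " compounds, ", nrow(x$resonances), " resonances, ",
      nrow(x$overlaps), " overlap annotations\n", sep = "")
  print(x$compounds, n = nrow(x$compounds))
  invisible(x)
}

#' @export
print.qnmr_compound <- function(x, ...) {
  cat(sprintf("<%s> %s (%s, %.2f g/mol, class %s)\n",
              x$abbrev, x$name, x$formula, x$molar_mass, x$cls))
  print(x$resonances)
  invisible(x)
}

#' Write a panel to a structured text file
#'
#' Panels are stored as human-editable YAML so that site-specific shift
#' calibrations or substrate extensions (e.g. switchgrass hydroxycinnamates)
#' are data edits, not code changes.
#'
#' @param panel a `qnmr_panel`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "qnmr_panel"))
  res <- panel$resonances
  doc <- list(
    version = panel$version,
    compounds = lapply(seq_len(nrow(panel$compounds)), function(i) {
      row <- panel$compounds[i, ]
      rr <- res[res$abbrev == row$abbrev, ]
      list(
        abbrev = row$abbrev, name = row$name, formula = row$formula,
        cls = row$cls,
        resonances = lapply(seq_len(nrow(rr)), function(k) {
          list(
            label = rr$label[k], center_ppm = rr$center_ppm[k],
            multiplicity = rr$multiplicity[k],
            j_hz = as.numeric(rr$j_hz[[k]]),
            n_protons = rr$n_protons[k],
            window = c(rr$window_low[k], rr$window_high[k]),
            width_ppm = rr$width_ppm[k],
            role = rr$role[k], primary = rr$primary[k]
          )
        })
      )
    }),
    overlaps = lapply(seq_len(nrow(panel$overlaps)), function(i) {
      as.list(panel$overlaps[i, ])
    })
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a panel from a structured text file
#'
#' @param path a YAML panel file as written by [write_panel()]
#' @return a validated `qnmr_panel`
#' @export
read_panel <- function(path) {
  doc <- yaml::read_yaml(path)
  compounds <- dplyr::bind_rows(lapply(doc$compounds, function(cc) {
    tibble::tibble(abbrev = cc$abbrev, name = cc$name, formula = cc$formula,
                   cls = cc$cls)
  }))
  compounds$molar_mass <- formula_mass(compounds$formula)
  resonances <- dplyr::bind_rows(lapply(doc$compounds, function(cc) {
    dplyr::bind_rows(lapply(cc$resonances, function(rr) {
      res_row(cc$abbrev, rr$label, rr$center_ppm, rr$multiplicity,
              as.numeric(rr$j_hz %||% numeric()), rr$n_protons,
              rr$window[1], rr$window[2], rr$role,
              primary = isTRUE(rr$primary), width = rr$width_ppm %||% 0.04)
    }))
  }))
  overlaps <- if (length(doc$overlaps)) {
    dplyr::bind_rows(lapply(doc$overlaps, tibble::as_tibble))
  } else {
    tibble::tibble(a = character(), b = character(), note = character())
  }
  p <- new_panel(compounds, resonances, overlaps, version = as.character(doc$version))
  validate_panel(p)
  p
}
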