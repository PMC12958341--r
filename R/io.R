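#' Read a processed spectrum from disk
#'
#' Supports a minimal JCAMP-DX dialect (AFFN `XYDATA=(X++(Y..Y))`, the
#' fixed-form layout written by [write_spectrum()] and by most vendor
#' exporters) and plain two-column ppm/intensity text (whitespace- or
#' comma-delimited, `#` comments).  The ppm axis is normalised to descending
#' order on read; intensities are unchanged apart from that reversal.
#'
#' @param path input file
#' @param fmt `"auto"` (by extension: `.jdx`/`.dx` is JCAMP), `"jcamp"` or
#'   `"xy_text"`
#' @return a `qnmr_spectrum`; if the file carries no spectrometer frequency
#'   a warning is issued and `sf_mhz` is `NA`
#' @export
read_spectrum <- function(path, fmt = c("auto", "jcamp", "xy_text")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(jdx|dx)$", tolower(path))) "jcamp" else "xy_text"
  }
  if (fmt == "jcamp") read_jcamp(path) else read_xy_text(path)
}

read_xy_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data lines in ", path, call. = FALSE)
  lines <- gsub(",", " ", lines[keep])
  first_bad <- NULL
  parsed <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < 2 || anyNA(v[1:2])) {
      if (is.null(first_bad)) first_bad <<- i
      return(NULL)
    }
    v[1:2]
  })
  if (!is.null(first_bad)) {
    stop("malformed ppm/intensity pair at data line ", first_bad, " of ",
         path, call. = FALSE)
  }
  m <- do.call(rbind, parsed)
  warning("no spectrometer frequency metadata in two-column text; sf_mhz unset",
          call. = FALSE)
  new_spectrum(m[, 1], m[, 2], sf_mhz = NA_real_,
               provenance = list(source = path, format = "xy_text"))
}

read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^##", ln)) {
      kv <- sub("^##", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) stop("malformed JCAMP label at line ", i, call. = FALSE)
      key <- toupper(trimws(substr(kv, 1, eq - 1)))
      val <- trimws(substr(kv, eq + 1, nchar(kv)))
      hdr[[key]] <- val
      if (key == "XYDATA") { data_start <- i + 1; break }
    }
  }
  if (is.na(data_start)) stop("no ##XYDATA= block found in ", path, call. = FALSE)
  need <- function(key) {
    if (is.null(hdr[[key]])) stop("JCAMP file missing ##", key, "=", call. = FALSE)
    as.numeric(hdr[[key]])
  }
  xfactor <- if (is.null(hdr$XFACTOR)) 1 else as.numeric(hdr$XFACTOR)
  yfactor <- if (is.null(hdr$YFACTOR)) 1 else as.numeric(hdr$YFACTOR)
  npoints <- need("NPOINTS")
  firstx <- need("FIRSTX")
  lastx <- need("LASTX")
  sf <- if (!is.null(hdr$.OBSERVE_FREQUENCY %||% hdr$`.OBSERVE FREQUENCY`)) {
    as.numeric(hdr$.OBSERVE_FREQUENCY %||% hdr$`.OBSERVE FREQUENCY`)
  } else NA_real_
  ys <- numeric(0)
  for (i in data_start:length(lines)) {
    ln <- lines[i]
    if (grepl("^##END", ln)) break
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (length(v) < 2 || anyNA(v)) {
      stop("malformed JCAMP data at line ", i, " of ", path, call. = FALSE)
    }
    ys <- c(ys, v[-1])
  }
  if (length(ys) != npoints) {
    stop(sprintf("JCAMP NPOINTS=%d but %d ordinates read", npoints, length(ys)),
         call. = FALSE)
  }
  x <- seq(firstx, lastx, length.out = npoints) * xfactor
  if (is.na(sf)) {
    warning("JCAMP file has no .OBSERVE FREQUENCY; sf_mhz unset", call. = FALSE)
  }
  new_spectrum(x, ys * yfactor, sf_mhz = sf,
               provenance = list(source = path, format = "jcamp"))
}

#' Write a spectrum to disk
#'
#' @param spec a `qnmr_spectrum`
#' @param path output file
#' @param fmt `"auto"` (by extension), `"jcamp"` or `"xy_text"`
#' @return `path`, invisibly
#' @export
write_spectrum <- function(spec, path, fmt = c("auto", "jcamp", "xy_text")) {
  stopifnot(inherits(spec, "qnmr_spectrum"))
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(jdx|dx)$", tolower(path))) "jcamp" else "xy_text"
  }
  if (fmt == "xy_text") {
    writeLines(c("# ppm intensity",
                 sprintf("%.8f %.10e", spec$ppm, spec$intensity)), path)
    return(invisible(path))
  }
  n <- nrow(spec)
  sf <- attr(spec, "sf_mhz")
  # JCAMP stores the trace from FIRSTX to LASTX; keep descending order.
  header <- c(
    "##TITLE=rcfqnmr spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##DATA CLASS=XYDATA",
    if (!is.na(sf)) sprintf("##.OBSERVE FREQUENCY=%.6f", sf),
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10f", spec$ppm[1]),
    sprintf("##LASTX=%.10f", spec$ppm[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))"
  )
  # Four ordinates per line in AFFN form.
  idx <- seq(1, n, by = 4)
  body <- vapply(idx, function(i) {
    j <- min(i + 3, n)
    paste(c(sprintf("%.10f", spec$ppm[i]),
            sprintf("%.10e", spec$intensity[i:j])), collapse = " ")
  }, character(1))
  writeLines(c(header, body, "##END="), path)
  invisible(path)
}
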