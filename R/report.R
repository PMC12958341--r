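#' Selectivity of a monomer group
#'
#' Selectivity expresses a group's share of the total monomer yield:
#' `100 * sum(group yields) / sum(all yields)`.
#'
#' @param results a data frame with columns `compound` and `yield_wt_pct`
#'   (a `qnmr_result` works directly)
#' @param group character vector of compound abbreviations
#' @return selectivity in percent
#' @examples
#' yields <- tibble::tibble(
#'   compound = c("PS", "PG", "PSOH", "PGOH", "OTHER"),
#'   yield_wt_pct = c(8.2, 5.26, 3.8, 2.9, 3.34)
#' )
#' selectivity(yields, c("PS", "PG"))
#' @export
selectivity <- function(results, group) {
  stopifnot(all(c("compound", "yield_wt_pct") %in% names(results)))
  total <- sum(results$yield_wt_pct, na.rm = TRUE)
  if (total <= 0) stop("total yield is zero; selectivity undefined", call. = FALSE)
  if (length(group) == 0) return(0)
  g <- sum(results$yield_wt_pct[results$compound %in% group], na.rm = TRUE)
  100 * g / total
}

#' Compare NMR yields against a reference method
#'
#' Matches two yield tables on sample and compound keys and computes
#' per-compound agreement statistics: the coefficient of determination both
#' about the identity line (pure agreement: predictions are the reference
#' values themselves) and from a least-squares fit (association), the mean
#' absolute deviation (wt%) and the mean relative deviation (%, denominator
#' = reference).  Unmatched keys are retained in the result, never silently
#' dropped.
#'
#' @param nmr,ref data frames with columns `sample`, `compound` and
#'   `yield_wt_pct`
#' @return an object of class `qnmr_comparison`: a list with tibbles
#'   `pairs`, `by_compound`, `overall` and `unmatched`
#' @export
compare_to_reference <- function(nmr, ref) {
  need <- c("sample", "compound", "yield_wt_pct")
  stopifnot(all(need %in% names(nmr)), all(need %in% names(ref)))
  nmr <- dplyr::select(tibble::as_tibble(nmr), dplyr::all_of(need))
  ref <- dplyr::select(tibble::as_tibble(ref), dplyr::all_of(need))
  pairs <- dplyr::inner_join(
    dplyr::rename(nmr, nmr_yield = "yield_wt_pct"),
    dplyr::rename(ref, ref_yield = "yield_wt_pct"),
    by = c("sample", "compound")
  )
  pairs <- dplyr::filter(pairs, !is.na(.data$nmr_yield), !is.na(.data$ref_yield))
  pairs <- dplyr::mutate(
    pairs,
    abs_dev = abs(.data$nmr_yield - .data$ref_yield),
    rel_dev_pct = ifelse(.data$ref_yield != 0,
                         100 * (.data$nmr_yield - .data$ref_yield) / .data$ref_yield,
                         NA_real_)
  )
  unmatched <- dplyr::bind_rows(
    dplyr::mutate(dplyr::anti_join(nmr, ref, by = c("sample", "compound")),
                  missing_from = "reference"),
    dplyr::mutate(dplyr::anti_join(ref, nmr, by = c("sample", "compound")),
                  missing_from = "nmr")
  )
  by_compound <- pairs |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n = dplyr::n(),
      mad = mean(.data$abs_dev),
      mean_rel_dev_pct = mean(abs(.data$rel_dev_pct), na.rm = TRUE),
      r2_identity = if (dplyr::n() >= 3) {
        1 - sum((.data$nmr_yield - .data$ref_yield)^2) /
          sum((.data$ref_yield - mean(.data$ref_yield))^2)
      } else NA_real_,
      r2_fit = if (dplyr::n() >= 3) {
        fit <- stats::lm(nmr_yield ~ ref_yield,
                         data = data.frame(nmr_yield = .data$nmr_yield,
                                           ref_yield = .data$ref_yield))
        suppressWarnings(summary(fit)$r.squared)  # exact fits warn
      } else NA_real_,
      note = if (dplyr::n() < 3) "fewer than 3 matched samples; R^2 omitted"
             else NA_character_,
      .groups = "drop"
    )
  overall <- tibble::tibble(
    n_pairs = nrow(pairs),
    mad = mean(pairs$abs_dev),
    mean_rel_dev_pct = mean(abs(pairs$rel_dev_pct), na.rm = TRUE),
    n_unmatched = nrow(unmatched)
  )
  structure(list(pairs = pairs, by_compound = by_compound, overall = overall,
                 unmatched = unmatched),
            class = "qnmr_comparison")
}

#' @export
print.qnmr_comparison <- function(x, ...) {
  cat(sprintf("<qnmr_comparison> %d matched pairs, %d unmatched keys\n",
              x$overall$n_pairs, x$overall$n_unmatched))
  cat(sprintf("  overall MAD %.3f wt%%, mean |rel dev| %.1f%%\n",
              x$overall$mad, x$overall$mean_rel_dev_pct))
  print(x$by_compound)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-compound comparison statistics
#' @param x a `qnmr_comparison`
#' @param ... unused
#' @return the per-compound statistics tibble
#' @method tidy qnmr_comparison
#' @export
tidy.qnmr_comparison <- function(x, ...) x$by_compound

#' One-row summary of a method comparison
#' @param x a `qnmr_comparison`
#' @param ... unused
#' @return a one-row tibble with overall MAD and relative deviation
#' @method glance qnmr_comparison
#' @export
glance.qnmr_comparison <- function(x, ...) x$overall

#' Tidy a quantification result
#' @param x a `qnmr_result`
#' @param ... unused
#' @return a plain tibble of the per-compound rows
#' @method tidy qnmr_result
#' @export
tidy.qnmr_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "qnmr_result")
  attr(out, "prep") <- NULL; attr(out, "corrections") <- NULL
  attr(out, "phenol") <- NULL; attr(out, "aliphatic") <- NULL
  attr(out, "linewidth_hz") <- NULL; attr(out, "noise") <- NULL
  attr(out, "hb_total_yield") <- NULL; attr(out, "sf_defaulted") <- NULL
  out
}

#' One-row summary of a quantification result
#' @param x a `qnmr_result`
#' @param ... unused
#' @return a one-row tibble: total yield, number of quantified and reliable
#'   compounds, pHBA+MP sum, phenol gating status and linewidth
#' @method glance qnmr_result
#' @export
glance.qnmr_result <- function(x, ...) {
  tibble::tibble(
    total_yield_wt_pct = sum(x$yield_wt_pct, na.rm = TRUE),
    n_quantified = sum(!is.na(x$yield_wt_pct)),
    n_reliable = sum(x$reliable, na.rm = TRUE),
    hb_total_yield = attr(x, "hb_total_yield"),
    phenol_interference = isTRUE(attr(x, "phenol")$detected),
    linewidth_hz = attr(x, "linewidth_hz")
  )
}
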