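#' Adjust nominal income by a consumer price index
#'
#' Removes inflation from reported fishery income so that years are
#' comparable. The default convention multiplies reported income by
#' CPI_t / CPI_T, where T is the series' reference year (its most recent
#' year unless set otherwise). The conventional deflation to reference-year
#' currency is the reciprocal ratio; it is available as
#' `deflation = "standard"` (RI × CPI_T / CPI_t). The two conventions agree
#' only when CPI_t = CPI_T; the choice is a documented switch, not a
#' silent default.
#'
#' The adjustment is linear in income; applying it twice is not the same as
#' applying it once.
#'
#' @param income_raw Nominal income value(s).
#' @param year Year(s) the income was reported in.
#' @param cpi A CPI series from [read_cpi()] or [cpi_series()].
#' @param deflation `"as-printed"` (CPI_t / CPI_T) or `"standard"`
#'   (CPI_T / CPI_t).
#' @return Adjusted income, same length as `income_raw`.
#' @export
cpi_adjust <- function(income_raw, year, cpi,
                       deflation = c("as-printed", "standard")) {
  deflation <- match.arg(deflation)
  ref_year <- attr(cpi, "reference_year") %||% max(cpi$year)
  idx <- match(year, cpi$year)
  if (anyNA(idx)) {
    abort_validation(sprintf(
      "no CPI value for year%s %s",
      if (sum(is.na(idx)) > 1) "s" else "",
      paste(unique(year[is.na(idx)]), collapse = ", ")
    ))
  }
  cpi_t <- cpi$cpi[idx]
  cpi_T <- cpi$cpi[match(ref_year, cpi$year)]
  ratio <- if (deflation == "as-printed") cpi_t / cpi_T else cpi_T / cpi_t
  income_raw * ratio
}

#' Aggregate landings and income records to annual series
#'
#' Sums landings and CPI-adjusted income per year for the requested species
#' scope. Species on the exclusion list are removed before aggregation:
#' fisheries under an informal closure affect reserve and control equally
#' and would dilute the before-after comparison.
#'
#' @param records Economic records from [read_econ()].
#' @param cpi CPI series; `NULL` leaves income unadjusted.
#' @param scope `"all"` or a single species code.
#' @param exclude Species codes dropped before aggregation.
#' @inheritParams cpi_adjust
#' @return A tibble (`year`, `landings_kg`, `income_adjusted`) sorted by
#'   year, with `scope` and `measure` metadata attributes.
#' @export
aggregate_econ <- function(records, cpi = NULL, scope = "all",
                           exclude = character(),
                           deflation = c("as-printed", "standard")) {
  deflation <- match.arg(deflation)
  df <- records[!records$species %in% exclude, ]
  if (!identical(scope, "all")) df <- df[df$species == scope, ]
  if (nrow(df) == 0) {
    abort_validation(sprintf(
      "no economic records left for scope '%s' after exclusions", scope
    ))
  }
  income_adj <- if (is.null(cpi)) df$income else {
    cpi_adjust(df$income, df$year, cpi, deflation = deflation)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(df, .income_adj = income_adj), .data$year),
    landings_kg = sum(.data$landings_kg),
    income_adjusted = sum(.data$.income_adj),
    .groups = "drop"
  )
  out <- out[order(out$year), ]
  attr(out, "scope") <- scope
  attr(out, "deflation") <- deflation
  out
}
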