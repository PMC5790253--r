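#' Read underwater visual-census survey records
#'
#' Reads transect-level survey observations from a CSV file and validates
#' them. Each row is one species observation on one transect; the reserved
#' species code `"NONE"` (with `count = 0`) marks a transect that was
#' surveyed but held no organisms of its taxon group, so that true zero
#' densities enter the analysis.
#'
#' Expected columns: `site`, `zone` (`reserve`/`control`), `year`,
#' `transect`, `group` (`fish`/`invertebrate`), `species`, `count`, and
#' optionally `length_cm` (fish total length), `temperature` (°C),
#' `visibility` (m), `depth` (m). Environmental covariates are assumed
#' constant within a transect.
#'
#' @param path Path to a CSV file with a header row.
#' @param traits Optional species trait table (see [read_traits()]). When
#'   supplied, species codes absent from it are reported via a warning and
#'   recorded in the `unknown_species` attribute; the records themselves are
#'   kept (they still inform richness and density).
#' @return A tibble of validated survey records.
#' @export
read_surveys <- function(path, traits = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_surveys(df, traits = traits, source = path)
}

#' Validate a survey record table
#'
#' The checks behind [read_surveys()], usable on an in-memory data frame
#' (e.g. simulator output). Errors cite the offending row numbers of the
#' input table.
#'
#' @param df Data frame of survey records.
#' @inheritParams read_surveys
#' @param source Label used in error messages.
#' @return A validated tibble with canonical column types.
#' @export
validate_surveys <- function(df, traits = NULL, source = "survey table") {
  require_columns(df, c("site", "zone", "year", "transect", "group",
                        "species", "count"), source)
  out <- tibble::as_tibble(df)
  for (col in c("length_cm", "temperature", "visibility", "depth")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
    out[[col]] <- as.numeric(out[[col]])
  }

  out$site <- as.character(out$site)
  out$zone <- tolower(as.character(out$zone))
  bad_zone <- which(!out$zone %in% ZONE_LEVELS)
  if (length(bad_zone) > 0) {
    abort_validation(sprintf(
      "%s: zone must be one of %s (row%s %s)", source,
      paste(ZONE_LEVELS, collapse = "/"),
      if (length(bad_zone) > 1) "s" else "",
      paste(head(bad_zone, 5), collapse = ", ")
    ))
  }
  out$group <- tolower(as.character(out$group))
  bad_group <- which(!out$group %in% GROUP_LEVELS)
  if (length(bad_group) > 0) {
    abort_validation(sprintf(
      "%s: group must be one of %s (row%s %s)", source,
      paste(GROUP_LEVELS, collapse = "/"),
      if (length(bad_group) > 1) "s" else "",
      paste(head(bad_group, 5), collapse = ", ")
    ))
  }
  out$year <- as.integer(out$year)
  out$transect <- as.character(out$transect)
  out$species <- as.character(out$species)
  out$count <- as.numeric(out$count)

  bad_count <- which(is.na(out$count) | out$count < 0 | out$count != round(out$count))
  if (length(bad_count) > 0) {
    abort_validation(sprintf(
      "%s: count must be a non-negative integer (row%s %s)", source,
      if (length(bad_count) > 1) "s" else "",
      paste(head(bad_count, 5), collapse = ", ")
    ))
  }
  zero_named <- which(out$count == 0 & out$species != NONE_CODE)
  if (length(zero_named) > 0) {
    abort_validation(sprintf(
      "%s: count 0 is only allowed for the reserved species code '%s' (row%s %s)",
      source, NONE_CODE,
      if (length(zero_named) > 1) "s" else "",
      paste(head(zero_named, 5), collapse = ", ")
    ))
  }
  bad_len <- which(!is.na(out$length_cm) & out$length_cm <= 0)
  if (length(bad_len) > 0) {
    abort_validation(sprintf(
      "%s: length_cm must be positive when recorded (row%s %s)", source,
      if (length(bad_len) > 1) "s" else "",
      paste(head(bad_len, 5), collapse = ", ")
    ))
  }
  out$count <- as.integer(out$count)

  if (!is.null(traits)) {
    unknown <- setdiff(unique(out$species), c(traits$species, NONE_CODE))
    if (length(unknown) > 0) {
      warning(sprintf(
        "%d species code%s not in the trait table (kept for richness/density, excluded from trait-based indicators): %s",
        length(unknown), if (length(unknown) > 1) "s are" else " is",
        paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
    attr(out, "unknown_species") <- unknown
  }
  out
}

#' Write survey records to CSV
#'
#' Writes the canonical survey CSV; [read_surveys()] on the result restores
#' the records field for field.
#'
#' @param records Survey record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(records, path) {
  cols <- c("site", "zone", "year", "transect", "group", "species", "count",
            "length_cm", "temperature", "visibility", "depth")
  readr::write_csv(records[, intersect(cols, names(records))], path)
  invisible(path)
}

#' Read a species trait table
#'
#' Traits feed the trait-dependent indicators: length–weight coefficients
#' (`lw_a` in g·cm^-b, `lw_b` dimensionless) for biomass, `trophic_level`
#' for mean trophic level, and `length_at_maturity_cm` for the percent of
#' mature organisms. Traits are only required for the indicators that use
#' them.
#'
#' @param path CSV with columns `species`, `group`, and any of `common_name`,
#'   `lw_a`, `lw_b`, `trophic_level`, `length_at_maturity_cm`.
#' @return A tibble of traits. Allometric exponents outside the usual
#'   \[2, 4\] range trigger a warning (they are usually typos).
#' @export
read_traits <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("species", "group"), path)
  out <- tibble::as_tibble(df)
  for (col in c("lw_a", "lw_b", "trophic_level", "length_at_maturity_cm")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
    out[[col]] <- as.numeric(out[[col]])
  }
  if (!"common_name" %in% names(out)) out$common_name <- out$species
  out$species <- as.character(out$species)
  out$group <- tolower(as.character(out$group))
  if (any(!is.na(out$lw_a) & out$lw_a <= 0) || any(!is.na(out$lw_b) & out$lw_b <= 0)) {
    abort_validation(sprintf("%s: length-weight coefficients must be positive", path))
  }
  odd_b <- !is.na(out$lw_b) & (out$lw_b < 2 | out$lw_b > 4)
  if (any(odd_b)) {
    warning(sprintf(
      "allometric exponent lw_b outside [2, 4] for: %s",
      paste(out$species[odd_b], collapse = ", ")
    ), call. = FALSE)
  }
  bad_tl <- !is.na(out$trophic_level) & out$trophic_level < 1
  if (any(bad_tl)) {
    abort_validation(sprintf("%s: trophic_level must be >= 1", path))
  }
  out
}

#' Read landings and income records
#'
#' One record per (year, month, species); `month` may be absent for annual
#' data. `income` is nominal currency, later deflated via [cpi_adjust()].
#'
#' @param path CSV with columns `year`, `species`, `landings_kg`, `income`,
#'   and optionally `month`.
#' @return A tibble of economic records.
#' @export
read_econ <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("year", "species", "landings_kg", "income"), path)
  out <- tibble::as_tibble(df)
  if (!"month" %in% names(out)) out$month <- NA_integer_
  out$year <- as.integer(out$year)
  out$month <- as.integer(out$month)
  out$species <- as.character(out$species)
  out$landings_kg <- as.numeric(out$landings_kg)
  out$income <- as.numeric(out$income)
  if (any(out$landings_kg < 0, na.rm = TRUE) || any(out$income < 0, na.rm = TRUE)) {
    abort_validation(sprintf("%s: landings_kg and income must be non-negative", path))
  }
  dup <- duplicated(out[, c("year", "month", "species")])
  if (any(dup)) {
    abort_validation(sprintf(
      "%s: duplicate (year, month, species) record%s at row%s %s",
      path, if (sum(dup) > 1) "s" else "", if (sum(dup) > 1) "s" else "",
      paste(head(which(dup), 5), collapse = ", ")
    ))
  }
  out
}

#' Read a consumer price index series
#'
#' @param path CSV with columns `year` and `cpi`.
#' @param reference_year Year whose currency the adjusted incomes are
#'   expressed in; defaults to the most recent year in the series.
#' @return A tibble (`year`, `cpi`) with a `reference_year` attribute.
#' @export
read_cpi <- function(path, reference_year = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("year", "cpi"), path)
  cpi_series(df$year, df$cpi, reference_year)
}

#' Construct a CPI series object
#'
#' @param year Integer years.
#' @param cpi Positive index values.
#' @param reference_year Reference year; default the most recent year.
#' @return A tibble (`year`, `cpi`) with a `reference_year` attribute.
#' @export
cpi_series <- function(year, cpi, reference_year = NULL) {
  year <- as.integer(year)
  cpi <- as.numeric(cpi)
  if (any(is.na(cpi)) || any(cpi <= 0)) {
    abort_validation("CPI values must be positive")
  }
  if (anyDuplicated(year)) abort_validation("duplicate years in CPI series")
  reference_year <- as.integer(reference_year %||% max(year))
  if (!reference_year %in% year) {
    abort_validation(sprintf("reference year %d absent from CPI series", reference_year))
  }
  out <- tibble::tibble(year = year, cpi = cpi)[order(year), ]
  attr(out, "reference_year") <- reference_year
  out
}

#' Read governance survey responses
#'
#' Accepts JSON (an array of objects with `code`, `value`, `narrative`) or a
#' CSV with the same columns. Codes are the governance questionnaire codes
#' `G1`–`G15` plus the two qualitative indicators that travel with them
#' (`B5` natural disturbance, `S3` alternative livelihoods).
#'
#' @param path Path to a `.json` or `.csv` file.
#' @return A tibble (`code`, `value`, `narrative`).
#' @export
read_governance <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  require_columns(df, c("code", "value"), path)
  out <- tibble::as_tibble(df)
  if (!"narrative" %in% names(out)) out$narrative <- NA_character_
  out$code <- toupper(as.character(out$code))
  allowed <- c(paste0("G", 1:15), "B5", "S3")
  bad <- setdiff(out$code, allowed)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "%s: unknown governance code%s: %s", path,
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")
    ))
  }
  out$value <- as.character(out$value)
  out$narrative <- as.character(out$narrative)
  out[, c("code", "value", "narrative")]
}

#' Reserve configuration
#'
#' Bundles what the evaluator must know about the reserve: when it was
#' implemented, which management objectives it was created for, and which
#' species are of particular management interest.
#'
#' @param reserve_name Reserve label used in reports.
#' @param implementation_year Year the reserve took effect.
#' @param objectives Character vector of management objectives (see
#'   [reserve_objectives()]); keys or full names.
#' @param target_species Species codes singled out for per-species
#'   indicators.
#' @param exclude_species Species removed from economic aggregation (e.g.
#'   fisheries under an informal closure, which receive the same treatment
#'   inside and outside the reserve).
#' @param reserve_size Optional area in km².
#' @return A list of class `reserve_config`.
#' @export
reserve_config <- function(reserve_name = "reserve",
                           implementation_year,
                           objectives,
                           target_species = character(),
                           exclude_species = character(),
                           reserve_size = NULL) {
  objectives <- normalize_objectives(objectives)
  if (length(objectives) == 0) abort_validation("objectives must be non-empty")
  structure(list(
    reserve_name = as.character(reserve_name),
    implementation_year = as.integer(implementation_year),
    objectives = objectives,
    target_species = as.character(target_species),
    exclude_species = as.character(exclude_species),
    reserve_size = reserve_size
  ), class = "reserve_config")
}

#' Check the BACI sampling design of a survey dataset
#'
#' A reserve can only be evaluated causally when surveys cover both a
#' control and the reserve zone, both before and after implementation.
#' Datasets violating any of those are hard failures that block the
#' difference-in-differences stage. Site-years with fewer than
#' `min_transects` transects (monitoring programs aim for at least 12–16
#' per site per year) and missing environmental covariates are soft
#' warnings.
#'
#' The check is pure: it never modifies the records.
#'
#' @param records Validated survey records.
#' @param implementation_year Reserve implementation year (or a
#'   [reserve_config()] in which case its year is used).
#' @param min_transects Soft minimum number of transects per site-year.
#' @param post_from Either `"impl-year"` (implementation year counts as
#'   after) or `"impl-year+1"`.
#' @return A `design_report` list: `pass`, `hard` (character vector of hard
#'   failures), `warnings`, and a `transects` tibble of per-site-year
#'   transect counts.
#' @export
validate_design <- function(records, implementation_year, min_transects = 12,
                            post_from = c("impl-year", "impl-year+1")) {
  if (inherits(implementation_year, "reserve_config")) {
    implementation_year <- implementation_year$implementation_year
  }
  post_from <- match.arg(post_from)
  if (nrow(records) == 0) abort_validation("no survey records supplied")

  hard <- character()
  warnings <- character()

  zones <- unique(records$zone)
  if (!"control" %in% zones) hard <- c(hard, "no control site in the data")
  if (!"reserve" %in% zones) hard <- c(hard, "no reserve site in the data")

  post <- is_post(records$year, implementation_year, post_from)
  if (!any(!post)) hard <- c(hard, "no pre-implementation (baseline) year in the data")
  if (!any(post)) hard <- c(hard, "no post-implementation year in the data")

  counts <- dplyr::summarise(
    dplyr::group_by(records, .data$site, .data$zone, .data$year),
    n_transects = dplyr::n_distinct(.data$transect),
    .groups = "drop"
  )
  thin <- counts[counts$n_transects < min_transects, ]
  if (nrow(thin) > 0) {
    warnings <- c(warnings, sprintf(
      "site-year %s/%d has %d transects (fewer than the recommended minimum of %d per site per year)",
      thin$site, thin$year, thin$n_transects, min_transects
    ))
  }
  for (cv in c("temperature", "visibility", "depth")) {
    n_missing <- sum(is.na(records[[cv]]))
    if (n_missing > 0) {
      warnings <- c(warnings, sprintf(
        "%d of %d records missing covariate '%s'", n_missing, nrow(records), cv
      ))
    }
  }

  structure(list(
    pass = length(hard) == 0,
    hard = hard,
    warnings = warnings,
    transects = counts,
    implementation_year = as.integer(implementation_year),
    min_transects = min_transects
  ), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("BACI design check:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$hard) > 0) cat(paste0("  hard failure: ", x$hard, "\n"), sep = "")
  if (length(x$warnings) > 0) cat(paste0("  warning: ", x$warnings, "\n"), sep = "")
  cat(sprintf("  %d site-year combinations, implementation year %d\n",
              nrow(x$transects), x$implementation_year))
  invisible(x)
}

# post-period indicator for a vector of years
is_post <- function(year, implementation_year, post_from = "impl-year") {
  if (post_from == "impl-year") year >= implementation_year else year > implementation_year
}
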