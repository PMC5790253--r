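#' Shannon diversity index
#'
#' H = -sum(p_s log p_s) over species proportions on one transect, using the
#' natural logarithm (the dominant ecological convention). The reserved
#' `"NONE"` code and zero counts are ignored.
#'
#' @param counts Named numeric vector of per-species counts.
#' @return H in nats, in \[0, log S\]; `NA` (with a warning) when no species
#'   was observed, so an empty transect is excluded from the diversity
#'   indicator rather than entered as a spurious zero.
#' @export
shannon_index <- function(counts) {
  counts <- keep_observed(counts)
  if (length(counts) == 0) {
    warning("no observed species; Shannon index undefined for this transect",
            call. = FALSE)
    return(NA_real_)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Species richness
#'
#' Number of distinct species with positive count on a transect; the
#' `"NONE"` placeholder does not count, so an empty transect has richness 0.
#'
#' @inheritParams shannon_index
#' @return Integer count of species.
#' @export
species_richness <- function(counts) {
  length(keep_observed(counts))
}

#' Total density (organisms per transect)
#'
#' Transect dimensions are survey-specific, so density is expressed per
#' transect rather than per unit area.
#'
#' @inheritParams shannon_index
#' @param scope `"all"` or a single species code to restrict to.
#' @return Sum of counts on the transect (0 for an empty transect).
#' @export
total_density <- function(counts, scope = "all") {
  counts <- keep_observed(counts)
  if (!identical(scope, "all")) counts <- counts[names(counts) == scope]
  if (length(counts) == 0) return(0)
  sum(counts)
}

#' Percent of measured organisms at or above length at first maturity
#'
#' Reflects the reproductive potential protected by the reserve. Ties at
#' exactly the maturity length count as mature.
#'
#' @param lengths Numeric vector of individual lengths (cm).
#' @param maturity_cm Length at first maturity (cm), positive.
#' @return Percent in \[0, 100\]; `NA` when no lengths were recorded (the
#'   transect is excluded rather than treated as 0% mature).
#' @export
mature_fraction <- function(lengths, maturity_cm) {
  if (!is_scalar_number(maturity_cm) || maturity_cm <= 0) {
    abort_validation("maturity_cm must be a positive number")
  }
  lengths <- lengths[!is.na(lengths)]
  if (any(lengths < 0)) abort_validation("lengths must be non-negative")
  if (length(lengths) == 0) return(NA_real_)
  100 * mean(lengths >= maturity_cm)
}

#' Abundance-weighted mean trophic level
#'
#' @inheritParams shannon_index
#' @param trophic_levels Named numeric vector mapping species to trophic
#'   level (>= 1). Species without a known trophic level are excluded with a
#'   warning.
#' @return Weighted mean sum(count_s TL_s) / sum(count_s); `NA` when no
#'   counted species has a known trophic level.
#' @export
mean_trophic_level <- function(counts, trophic_levels) {
  counts <- keep_observed(counts)
  tl <- trophic_levels[names(counts)]
  known <- !is.na(tl)
  if (length(counts) > 0 && any(!known)) {
    warning(sprintf(
      "no trophic level for: %s (excluded from mean trophic level)",
      paste(names(counts)[!known], collapse = ", ")
    ), call. = FALSE)
  }
  counts <- counts[known]
  tl <- as.numeric(tl[known])
  if (length(counts) == 0) return(NA_real_)
  sum(counts * tl) / sum(counts)
}

#' Transect biomass from length-weight allometry
#'
#' Individual weight follows the standard fisheries allometry
#' W = a L^b (W in grams for a in g·cm^-b and L in cm); transect biomass is
#' the sum over organisms, reported in kg per transect. Organisms without a
#' recorded length use the mean length of conspecifics on the same transect
#' when one exists, otherwise they are excluded with a warning.
#'
#' @param observations Data frame with columns `species`, `length_cm`, and
#'   optionally `count` (number of organisms the row represents, default 1).
#' @param traits Trait table with `species`, `lw_a`, `lw_b`.
#' @return Biomass in kg; 0 for an empty transect; `NA` when organisms were
#'   observed but no species has length-weight coefficients.
#' @export
transect_biomass <- function(observations, traits) {
  obs <- tibble::as_tibble(observations)
  if (!"count" %in% names(obs)) obs$count <- 1L
  obs <- obs[obs$species != NONE_CODE & obs$count > 0, ]
  if (nrow(obs) == 0) return(0)

  tr <- traits[match(obs$species, traits$species), c("lw_a", "lw_b")]
  has_traits <- !is.na(tr$lw_a) & !is.na(tr$lw_b)
  if (!any(has_traits)) {
    warning("no length-weight coefficients for any observed species; biomass undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (any(!has_traits)) {
    warning(sprintf(
      "no length-weight coefficients for: %s (excluded from biomass)",
      paste(unique(obs$species[!has_traits]), collapse = ", ")
    ), call. = FALSE)
  }
  obs <- obs[has_traits, ]
  tr <- tr[has_traits, ]

  # fill missing lengths with the species mean length on this transect
  len <- obs$length_cm
  if (anyNA(len)) {
    sp_mean <- tapply(
      rep(len, obs$count), rep(obs$species, obs$count),
      function(x) mean(x, na.rm = TRUE)
    )
    fill <- as.numeric(sp_mean[obs$species])
    len[is.na(len)] <- fill[is.na(len)]
    if (anyNA(len)) {
      warning(sprintf(
        "organisms of %s have no length on this transect (excluded from biomass)",
        paste(unique(obs$species[is.na(len)]), collapse = ", ")
      ), call. = FALSE)
    }
  }
  keep <- !is.na(len)
  if (!any(keep)) return(NA_real_)
  sum(obs$count[keep] * tr$lw_a[keep] * len[keep]^tr$lw_b[keep]) / 1000
}

INDICATOR_LABELS <- c(
  B1 = "Shannon diversity index",
  B2 = "Species richness",
  B3 = "Density of mature organisms",
  B4 = "Density",
  B5 = "Natural disturbance",
  B6 = "Mean trophic level",
  B7 = "Biomass",
  S1 = "Total landings",
  S2 = "Income from total landings",
  S3 = "Alternative economic opportunities"
)

#' Compute the per-transect indicator table
#'
#' Produces the response variable of the BACI regression: one value per
#' (indicator, taxon group, species scope, transect). Community indicators
#' B1 (Shannon diversity), B2 (richness) and B4 (density) are computed
#' separately for the fish and invertebrate communities; the
#' length-structured indicators B3 (percent mature), B6 (mean trophic
#' level) and B7 (biomass) are computed for fish, whose lengths are
#' recorded. Density (B4) and biomass (B7) are additionally emitted per
#' target species.
#'
#' Indicators whose required traits are absent are skipped with a warning
#' and listed in the `skipped` attribute. Undefined transect values (e.g.
#' Shannon on an empty transect) propagate as excluded rows, never as
#' zeros.
#'
#' @param records Validated survey records.
#' @param traits Species trait table ([read_traits()]); may be `NULL` when
#'   only B1/B2/B4 are requested.
#' @param indicators Subset of `c("B1","B2","B3","B4","B6","B7")`.
#' @param target_species Species codes for per-species density/biomass
#'   variants.
#' @return Tibble with columns `indicator`, `taxon`, `scope`, `site`,
#'   `zone`, `year`, `transect`, `value`, `temperature`, `visibility`,
#'   `depth`.
#' @export
compute_indicator_table <- function(records, traits = NULL,
                                    indicators = c("B1", "B2", "B3", "B4", "B6", "B7"),
                                    target_species = character()) {
  indicators <- match.arg(indicators, several.ok = TRUE)
  skipped <- character()

  # one row per transect per taxon group, with its covariates
  transects <- dplyr::summarise(
    dplyr::group_by(records, .data$site, .data$zone, .data$year,
                    .data$transect, .data$group),
    temperature = first_non_na(.data$temperature),
    visibility = first_non_na(.data$visibility),
    depth = first_non_na(.data$depth),
    .groups = "drop"
  )

  key <- function(df) paste(df$site, df$zone, df$year, df$transect, df$group, sep = "\r")
  records$.key <- key(records)
  transects$.key <- key(transects)
  by_transect <- split(records, records$.key)
  by_transect <- by_transect[transects$.key]

  trait_row <- function(sp, col) {
    if (is.null(traits)) return(NA_real_)
    as.numeric(traits[[col]][match(sp, traits$species)])
  }

  rows <- list()
  emit <- function(code, taxon, scope, values, which_transects) {
    tt <- transects[which_transects, ]
    rows[[length(rows) + 1]] <<- tibble::tibble(
      indicator = code, taxon = taxon, scope = scope,
      site = tt$site, zone = tt$zone, year = tt$year, transect = tt$transect,
      value = as.numeric(values),
      temperature = tt$temperature, visibility = tt$visibility, depth = tt$depth
    )
  }

  counts_of <- function(df) {
    cc <- tapply(df$count, df$species, sum)
    setNames(as.numeric(cc), names(cc))
  }

  for (taxon in intersect(GROUP_LEVELS, unique(transects$group))) {
    idx <- which(transects$group == taxon)
    tx <- by_transect[idx]
    counts_list <- lapply(tx, counts_of)

    if ("B1" %in% indicators) {
      vals <- vapply(counts_list, function(cc) suppressWarnings(shannon_index(cc)),
                     numeric(1))
      emit("B1", taxon, "all", vals, idx)
    }
    if ("B2" %in% indicators) {
      emit("B2", taxon, "all", vapply(counts_list, species_richness, numeric(1)), idx)
    }
    if ("B4" %in% indicators) {
      emit("B4", taxon, "all", vapply(counts_list, total_density, numeric(1)), idx)
      for (sp in target_species) {
        sp_group <- species_group(sp, records, traits)
        if (!identical(sp_group, taxon)) next
        emit("B4", taxon, sp,
             vapply(counts_list, total_density, numeric(1), scope = sp), idx)
      }
    }

    if (taxon == "fish") {
      if ("B3" %in% indicators) {
        if (is.null(traits) || all(is.na(traits$length_at_maturity_cm))) {
          skipped <- c(skipped, "B3: no length-at-maturity traits available")
        } else {
          vals <- vapply(tx, function(df) {
            mat <- trait_row(df$species, "length_at_maturity_cm")
            ok <- !is.na(df$length_cm) & !is.na(mat) & df$species != NONE_CODE
            if (!any(ok)) return(NA_real_)
            n <- df$count[ok]
            100 * sum(n * (df$length_cm[ok] >= mat[ok])) / sum(n)
          }, numeric(1))
          emit("B3", taxon, "all", vals, idx)
        }
      }
      if ("B6" %in% indicators) {
        if (is.null(traits) || all(is.na(traits$trophic_level))) {
          skipped <- c(skipped, "B6: no trophic-level traits available")
        } else {
          tl <- setNames(traits$trophic_level, traits$species)
          vals <- vapply(counts_list, function(cc) {
            suppressWarnings(mean_trophic_level(cc, tl))
          }, numeric(1))
          emit("B6", taxon, "all", vals, idx)
        }
      }
      if ("B7" %in% indicators) {
        if (is.null(traits) || all(is.na(traits$lw_a) | is.na(traits$lw_b))) {
          skipped <- c(skipped, "B7: no length-weight traits available")
        } else {
          vals <- vapply(tx, function(df) {
            suppressWarnings(transect_biomass(df, traits))
          }, numeric(1))
          emit("B7", taxon, "all", vals, idx)
          for (sp in target_species) {
            if (!identical(species_group(sp, records, traits), "fish")) next
            vals <- vapply(tx, function(df) {
              suppressWarnings(transect_biomass(df[df$species == sp, ], traits))
            }, numeric(1))
            emit("B7", taxon, sp, vals, idx)
          }
        }
      }
    }
  }

  if (length(skipped) > 0) {
    warning(paste("indicator(s) skipped:", paste(skipped, collapse = "; ")),
            call. = FALSE)
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    indicator = character(), taxon = character(), scope = character(),
    site = character(), zone = character(), year = integer(),
    transect = character(), value = numeric(), temperature = numeric(),
    visibility = numeric(), depth = numeric()
  )
  attr(out, "skipped") <- skipped
  out
}

#' Write an indicator table as tidy CSV
#'
#' @param table Output of [compute_indicator_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

# drop the NONE placeholder and non-positive counts
keep_observed <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  counts[names(counts) != NONE_CODE]
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else x[1]
}

# which taxon group a species belongs to, from the records first, traits second
species_group <- function(sp, records, traits) {
  g <- unique(records$group[records$species == sp])
  if (length(g) == 1) return(g)
  if (!is.null(traits)) {
    g <- traits$group[match(sp, traits$species)]
    if (!is.na(g)) return(g)
  }
  NA_character_
}
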