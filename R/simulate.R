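#' Default simulated species pool
#'
#' A small temperate-reef community of the kind recorded by visual-census
#' monitoring: five fish species (with individual lengths) and the four
#' commercially important invertebrates (lobster, urchin, snail, sea
#' cucumber, counted without lengths). Mean per-transect abundances,
#' negative-binomial dispersions, length distributions and traits are
#' plausible field magnitudes chosen once for the simulator.
#'
#' @return A trait-and-abundance tibble usable as `species` in
#'   [simulation_spec()] and (columns `species`..`length_at_maturity_cm`) as
#'   a trait table for [compute_indicator_table()].
#' @export
default_species_pool <- function() {
  tibble::tibble(
    species = c("sheephead", "kelp_bass", "senorita", "garibaldi", "perch",
                "lobster", "urchin", "snail", "cucumber"),
    group = c(rep("fish", 5), rep("invertebrate", 4)),
    common_name = c("California sheephead", "Kelp bass", "Senorita",
                    "Garibaldi", "Surfperch", "Spiny lobster",
                    "Red sea urchin", "Wavy turban snail", "Sea cucumber"),
    mean_count = c(2, 4, 10, 3, 6, 3, 25, 12, 8),
    dispersion = c(2, 3, 4, 2, 3, 2, 5, 4, 4),
    mean_length_cm = c(35, 28, 15, 20, 18, NA, NA, NA, NA),
    sd_length_cm = c(8, 6, 3, 4, 4, NA, NA, NA, NA),
    trophic_level = c(3.6, 3.8, 3.1, 2.9, 3.2, 2.6, 2.0, 2.1, 2.2),
    lw_a = c(0.014, 0.012, 0.010, 0.020, 0.015, NA, NA, NA, NA),
    lw_b = c(3.04, 3.10, 2.95, 3.00, 3.05, NA, NA, NA, NA),
    length_at_maturity_cm = c(20, 22, 10, 15, 12, NA, NA, NA, NA)
  )
}

#' Specification for a simulated BACI monitoring program
#'
#' Describes the study conditions a simulated dataset emulates: the survey
#' years and reserve implementation year, the per-site-per-year sampling
#' effort (a monitoring program aims for at least 12–16 transects), the
#' species pool, covariate distributions, the noise model, and — crucially —
#' the injected reserve effect, an additive post-x-reserve shift in total
#' density per taxon group. The injected value is the true
#' difference-in-differences interaction coefficient for the density
#' indicator of that group, which is what makes simulated data a
#' ground-truth test of the inference machinery.
#'
#' @param years Integer vector of survey years.
#' @param implementation_year Reserve implementation year (must fall within
#'   or adjacent to `years`).
#' @param transects_per_site_year Number of transects per site per year; a
#'   length-2 vector gives a range sampled uniformly per site-year.
#' @param species Species pool tibble (see [default_species_pool()]).
#' @param density_effect Named numeric: additive shift in expected total
#'   organisms per transect in the reserve zone after implementation, per
#'   taxon group (e.g. `c(fish = 0, invertebrate = 10)`), distributed across
#'   species proportionally to their mean abundance.
#' @param noise `list(model = "nb")` for negative-binomial counts (field
#'   counts are overdispersed, which stresses the robust-SE machinery) or
#'   `list(model = "gaussian", sd = <number>)` for homoskedastic rounded
#'   Gaussian counts, useful for calibration checks of the t test.
#' @param zone_ratio Multiplicative baseline difference of the reserve zone
#'   (1 = zones identical before implementation).
#' @param year_effect_sd SD of a log-scale year shock shared by both zones
#'   (common temporal trend; the parallel-trends assumption holds by
#'   construction).
#' @param covariates List of `c(mean, sd)` for `temperature` (°C),
#'   `visibility` (m), `depth` (m).
#' @param post_from Post-period convention, as in [fit_did()].
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(years = 2006:2016,
                            implementation_year = 2012,
                            transects_per_site_year = 16,
                            species = default_species_pool(),
                            density_effect = c(fish = 0, invertebrate = 0),
                            noise = list(model = "nb"),
                            zone_ratio = 1,
                            year_effect_sd = 0.05,
                            covariates = list(temperature = c(18, 1.5),
                                              visibility = c(10, 2),
                                              depth = c(12, 3)),
                            post_from = "impl-year") {
  years <- sort(as.integer(years))
  implementation_year <- as.integer(implementation_year)
  if (implementation_year < min(years) - 1 || implementation_year > max(years) + 1) {
    abort_validation("implementation_year must fall within (or be adjacent to) the survey years")
  }
  if (any(transects_per_site_year < 1)) {
    abort_validation("transects_per_site_year must be >= 1")
  }
  structure(list(
    years = years, implementation_year = implementation_year,
    transects_per_site_year = transects_per_site_year,
    species = species, density_effect = density_effect,
    noise = noise, zone_ratio = zone_ratio, year_effect_sd = year_effect_sd,
    covariates = covariates, post_from = post_from
  ), class = "simulation_spec")
}

#' Simulate a BACI underwater-survey dataset
#'
#' Draws per-transect species counts (and fish lengths) for a two-zone
#' (reserve/control) multi-year monitoring program under a
#' [simulation_spec()]. The expected total density per taxon group is a
#' shared year effect times the group baseline, plus the injected
#' post-x-reserve shift; counts are negative-binomial (or rounded Gaussian)
#' around the species-level means. Covariates are drawn per transect.
#' Output is fully determined by `seed`.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed.
#' @return A validated survey-record tibble (as from [read_surveys()]).
#' @export
simulate_baci <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)

  years <- spec$years
  pool <- spec$species
  year_mult <- setNames(exp(rnorm(length(years), 0, spec$year_effect_sd)),
                        as.character(years))

  # grid of transect units
  grid <- list()
  for (zone in ZONE_LEVELS) {
    for (yr in years) {
      n_t <- spec$transects_per_site_year
      if (length(n_t) == 2) n_t <- sample(seq(n_t[1], n_t[2]), 1)
      grid[[length(grid) + 1]] <- tibble::tibble(
        site = paste0(zone, "_site"), zone = zone, year = yr,
        transect = sprintf("T%02d", seq_len(n_t))
      )
    }
  }
  grid <- dplyr::bind_rows(grid)
  n <- nrow(grid)
  cv <- spec$covariates
  grid$temperature <- rnorm(n, cv$temperature[1], cv$temperature[2])
  grid$visibility <- pmax(0.5, rnorm(n, cv$visibility[1], cv$visibility[2]))
  grid$depth <- pmax(1, rnorm(n, cv$depth[1], cv$depth[2]))

  post_res <- is_post(grid$year, spec$implementation_year, spec$post_from) &
    grid$zone == "reserve"
  base_mult <- ifelse(grid$zone == "reserve", spec$zone_ratio, 1) *
    year_mult[as.character(grid$year)]

  records <- list()
  for (g in intersect(GROUP_LEVELS, unique(pool$group))) {
    sp <- pool[pool$group == g, ]
    group_base <- sum(sp$mean_count)
    shift <- unname(spec$density_effect[g])
    if (is.na(shift)) shift <- 0
    share <- sp$mean_count / group_base
    counts <- matrix(0L, nrow = n, ncol = nrow(sp))
    for (j in seq_len(nrow(sp))) {
      mu <- share[j] * (group_base * base_mult + shift * post_res)
      mu <- pmax(mu, 1e-8)
      counts[, j] <- if (identical(spec$noise$model, "gaussian")) {
        as.integer(pmax(0, round(rnorm(n, mu, spec$noise$sd * sqrt(share[j])))))
      } else {
        rnbinom(n, mu = mu, size = sp$dispersion[j])
      }
    }

    for (j in seq_len(nrow(sp))) {
      pos <- which(counts[, j] > 0)
      if (length(pos) == 0) next
      if (!is.na(sp$mean_length_cm[j])) {
        # fish: one row per organism with an individual length
        reps <- rep(pos, counts[pos, j])
        rec <- grid[reps, ]
        rec$group <- g
        rec$species <- sp$species[j]
        rec$count <- 1L
        rec$length_cm <- pmax(1, rnorm(length(reps), sp$mean_length_cm[j],
                                       sp$sd_length_cm[j]))
      } else {
        rec <- grid[pos, ]
        rec$group <- g
        rec$species <- sp$species[j]
        rec$count <- counts[pos, j]
        rec$length_cm <- NA_real_
      }
      records[[length(records) + 1]] <- rec
    }
    # transects with no organisms of this group get the NONE placeholder
    empty <- which(rowSums(counts) == 0)
    if (length(empty) > 0) {
      rec <- grid[empty, ]
      rec$group <- g
      rec$species <- NONE_CODE
      rec$count <- 0L
      rec$length_cm <- NA_real_
      records[[length(records) + 1]] <- rec
    }
  }

  out <- dplyr::bind_rows(records)
  out <- out[, c("site", "zone", "year", "transect", "group", "species",
                 "count", "length_cm", "temperature", "visibility", "depth")]
  out <- out[order(out$zone, out$year, out$transect, out$group, out$species), ]
  validate_surveys(out, source = "simulated surveys")
}

#' Simulate annual landings/income records and a CPI series
#'
#' Generates one economic record per year for one species, with a
#' before/after level shift equal (in expectation) to the injected value on
#' the inflation-adjusted scale, plus optional Gaussian noise. The nominal
#' income written to the records is back-computed through the CPI ratio so
#' that [cpi_adjust()] recovers the intended adjusted series.
#'
#' @param years Integer vector of years.
#' @param implementation_year Reserve implementation year.
#' @param base Named numeric `c(landings = , income = )`: pre-implementation
#'   expected annual totals (kg and currency at reference-year prices).
#' @param shift Named numeric `c(landings = , income = )`: post-period level
#'   shifts (the true before-after coefficients).
#' @param noise_sd Named numeric `c(landings = , income = )` Gaussian SDs.
#' @param inflation Annual CPI growth rate.
#' @param species Species code for the records.
#' @param post_from Post-period convention.
#' @param seed Integer seed.
#' @return `list(econ = <records tibble>, cpi = <CPI series>)`.
#' @export
simulate_econ <- function(years = 2002:2016, implementation_year = 2012,
                          base = c(landings = 100, income = 5000),
                          shift = c(landings = 0, income = 0),
                          noise_sd = c(landings = 0, income = 0),
                          inflation = 0.04, species = "lobster",
                          post_from = "impl-year", seed = 1) {
  set.seed(seed)
  years <- sort(as.integer(years))
  if (implementation_year <= min(years) || implementation_year > max(years)) {
    abort_validation("implementation_year must leave years on both sides of the split")
  }
  post <- as.numeric(is_post(years, implementation_year, post_from))
  n <- length(years)
  cpi <- cpi_series(years, 100 * (1 + inflation)^(years - min(years)))
  ref <- attr(cpi, "reference_year")

  landings <- pmax(0, base[["landings"]] + shift[["landings"]] * post +
                     rnorm(n, 0, noise_sd[["landings"]]))
  income_adj <- pmax(0, base[["income"]] + shift[["income"]] * post +
                       rnorm(n, 0, noise_sd[["income"]]))
  # nominal income such that the as-printed CPI adjustment recovers income_adj
  ratio <- cpi$cpi[match(years, cpi$year)] / cpi$cpi[match(ref, cpi$year)]
  econ <- tibble::tibble(
    year = years, month = NA_integer_, species = species,
    landings_kg = landings, income = income_adj / ratio
  )
  list(econ = econ, cpi = cpi)
}

#' Write a self-contained fixture bundle to disk
#'
#' Generates and writes a complete, loadable input set: surveys, species
#' traits, landings, CPI, governance responses and a run configuration,
#' ready for [run_evaluate()] or the command-line interface.
#'
#' Presets: `"minimal"` is the smallest design the sampling guidance
#' recommends (2 years around implementation, 12 transects per site per
#' year); `"natividad_like"` mimics the shape of a decade-long
#' community-monitoring case (11 survey years, 12–27 transects per site per
#' year, a fish community plus four target invertebrates with positive
#' injected invertebrate effects, 15 years of landings). All values are
#' simulated — no real monitoring data are included.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"minimal"` or `"natividad_like"`.
#' @param seed Integer seed.
#' @return Named list of file paths, invisibly.
#' @export
make_fixture_bundle <- function(dir, preset = c("minimal", "natividad_like"),
                                seed = 1) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  if (preset == "minimal") {
    pool <- default_species_pool()[c(2, 3, 7, 8), ]
    spec <- simulation_spec(
      years = 2011:2012, implementation_year = 2012,
      transects_per_site_year = 12, species = pool,
      density_effect = c(fish = 0, invertebrate = 0)
    )
    impl <- 2012L
    targets <- character()
    econ_years <- 2008:2015
  } else {
    pool <- default_species_pool()
    spec <- simulation_spec(
      years = 2006:2016, implementation_year = 2012,
      transects_per_site_year = c(12, 27), species = pool,
      density_effect = c(fish = 2, invertebrate = 15),
      zone_ratio = 1.1
    )
    impl <- 2012L
    targets <- c("lobster", "urchin", "snail", "cucumber")
    econ_years <- 2002:2016
  }

  surveys <- simulate_baci(spec, seed = seed)
  econ_parts <- lapply(seq_along(unique(pool$species[pool$group == "invertebrate"])),
    function(i) {
      sp <- pool$species[pool$group == "invertebrate"][i]
      simulate_econ(
        years = econ_years, implementation_year = impl,
        base = c(landings = 5000 * i, income = 20000 * i),
        shift = c(landings = if (preset == "minimal") 0 else 500 * (3 - i),
                  income = if (preset == "minimal") 0 else 2000 * (3 - i)),
        noise_sd = c(landings = 300, income = 1500),
        species = sp, seed = derive_seed(seed, i)
      )
    })
  econ <- dplyr::bind_rows(lapply(econ_parts, `[[`, "econ"))
  cpi <- econ_parts[[1]]$cpi

  governance <- tibble::tibble(
    code = c(paste0("G", 1:15), "B5", "S3"),
    value = c("managed_access", "stable", "no", "community reserve", "low",
              "no", "two land stations with radar and 24/7 patrol boats",
              "adequate", "sited on formerly productive grounds",
              "yes", "cooperative_and_federation", "high", "yes",
              "positive", "positive",
              "no major storm or hypoxia event during the survey period",
              "few"),
    narrative = NA_character_
  )

  paths <- list(
    surveys = file.path(dir, "surveys.csv"),
    traits = file.path(dir, "species_traits.csv"),
    econ = file.path(dir, "landings.csv"),
    cpi = file.path(dir, "cpi.csv"),
    governance = file.path(dir, "governance.json"),
    config = file.path(dir, "config.yaml")
  )
  write_surveys(surveys, paths$surveys)
  readr::write_csv(
    pool[, c("species", "group", "common_name", "lw_a", "lw_b",
             "trophic_level", "length_at_maturity_cm")],
    paths$traits
  )
  readr::write_csv(econ, paths$econ)
  readr::write_csv(cpi, paths$cpi)
  jsonlite::write_json(governance, paths$governance, dataframe = "rows",
                       na = "null", auto_unbox = TRUE, pretty = TRUE)
  config <- list(
    reserve_name = if (preset == "minimal") "minimal_reserve" else "simulated_island_reserve",
    implementation_year = impl,
    objectives = c("preserve_biodiversity", "improve_fishery_production",
                   "recover_economic_species"),
    target_species = as.list(targets),
    exclude_species = list(),
    surveys = "surveys.csv", traits = "species_traits.csv",
    econ = "landings.csv", cpi = "cpi.csv", governance = "governance.json",
    robust = "HC1", post_from = "impl-year", scoring = "sign",
    deflation = "as-printed", output_dir = "results"
  )
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
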