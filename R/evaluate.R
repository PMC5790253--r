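#' Run the full reserve evaluation workflow
#'
#' Orchestrates the whole pipeline from raw input files to the scorecard
#' and technical report: read and validate all inputs, check the BACI
#' sampling design, compute the per-transect indicator table, fit the
#' difference-in-differences model per indicator (and the before-after
#' model per economic series), score governance responses, build the
#' scorecard, and render the artifacts.
#'
#' @param config Either a path to a YAML configuration file or a named
#'   list. Recognized fields: `surveys`, `traits`, `econ`, `cpi`,
#'   `governance` (input paths, resolved relative to the YAML file's
#'   directory), `reserve_name`, `implementation_year`, `objectives`,
#'   `target_species`, `exclude_species`, `robust` (HC0–HC3, default HC1),
#'   `post_from` (`impl-year`/`impl-year+1`), `scoring` (`sign`/`strict`),
#'   `deflation` (`as-printed`/`standard`), `min_transects` (default 12),
#'   `allow_design_failure` (default `FALSE`), `output_dir`, `plots`,
#'   `rubric` (path to a custom governance rubric).
#' @param ... Named overrides applied on top of the configuration.
#' @return A list with `status` (0 success, 2 design hard-failure),
#'   `design`, `scorecard`, `fits`, `indicator_table`, `artifacts`, `log`
#'   (character vector of per-step notes: dropped rows, skipped indicators,
#'   decision flags in effect). Status 2 is returned — with the design
#'   report — instead of computing inference when the BACI design fails
#'   hard and `allow_design_failure` is not set.
#' @export
run_evaluate <- function(config, ...) {
  cfg <- load_run_config(config, ...)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  note("robust SE flavor: %s; post-period from: %s; scoring: %s; deflation: %s",
       cfg$robust, cfg$post_from, cfg$scoring, cfg$deflation)

  traits <- if (!is.null(cfg$traits)) read_traits(cfg$traits) else NULL
  surveys <- withCallingHandlers(
    read_surveys(cfg$surveys, traits = traits),
    warning = function(w) {
      note("surveys: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  design <- validate_design(surveys, cfg$implementation_year,
                            min_transects = cfg$min_transects,
                            post_from = cfg$post_from)
  for (w in design$warnings) note("design: %s", w)
  if (!design$pass) {
    for (h in design$hard) note("design hard failure: %s", h)
    if (!isTRUE(cfg$allow_design_failure)) {
      message("BACI design check failed: ",
              paste(design$hard, collapse = "; "))
      return(list(status = 2L, design = design, scorecard = NULL,
                  fits = list(), indicator_table = NULL,
                  artifacts = list(), log = log))
    }
    note("design failure overridden by allow_design_failure")
  }

  selected <- indicators_for_objectives(cfg$objectives)
  note("objectives selected indicators: %s", paste(selected, collapse = ", "))
  bio_codes <- intersect(c("B1", "B2", "B3", "B4", "B6", "B7"),
                         sub("\\*$", "", selected))
  want_targets <- any(grepl("\\*$", selected))

  indicator_table <- withCallingHandlers(
    compute_indicator_table(
      surveys, traits = traits, indicators = bio_codes,
      target_species = if (want_targets) cfg$target_species else character()
    ),
    warning = function(w) {
      note("indicators: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  # one DiD fit per (indicator, taxon, scope)
  fits <- list()
  effects <- list()
  cells <- unique(indicator_table[, c("indicator", "taxon", "scope")])
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    df <- dplyr::semi_join(indicator_table, cell,
                           by = c("indicator", "taxon", "scope"))
    nm <- paste0(cell$indicator, "_", cell$taxon,
                 if (cell$scope != "all") paste0("_", cell$scope) else "")
    fit <- tryCatch(
      withCallingHandlers(
        fit_did(df, cfg$implementation_year, robust = cfg$robust,
                post_from = cfg$post_from),
        message = function(m) {
          note("%s: %s", nm, trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        }
      ),
      error = function(e) {
        note("%s: fit skipped (%s)", nm, conditionMessage(e))
        NULL
      }
    )
    if (is.null(fit)) next
    if (fit$design$n_dropped > 0) {
      note("%s: dropped %d rows with missing covariates", nm, fit$design$n_dropped)
    }
    fits[[nm]] <- fit
    effects[[nm]] <- tibble::tibble(
      indicator = cell$indicator, taxon = cell$taxon, scope = cell$scope,
      fit$effect
    )
  }

  # economic series: before-after fits for S1 (landings) and S2 (income)
  if (!is.null(cfg$econ)) {
    econ <- read_econ(cfg$econ)
    cpi <- if (!is.null(cfg$cpi)) read_cpi(cfg$cpi) else NULL
    if (length(cfg$exclude_species) > 0) {
      note("economics: excluding species %s", paste(cfg$exclude_species, collapse = ", "))
    }
    scopes <- "all"
    if (any(grepl("^S[12]\\*$", selected))) {
      scopes <- c(scopes, intersect(cfg$target_species, unique(econ$species)))
    }
    for (sc in scopes) {
      series <- tryCatch(
        aggregate_econ(econ, cpi = cpi, scope = sc,
                       exclude = cfg$exclude_species, deflation = cfg$deflation),
        error = function(e) {
          note("economics scope %s: %s", sc, conditionMessage(e))
          NULL
        }
      )
      if (is.null(series)) next
      for (measure in c("S1", "S2")) {
        if (!any(startsWith(selected, measure))) next
        col <- if (measure == "S1") "landings_kg" else "income_adjusted"
        nm <- paste0(measure, if (sc != "all") paste0("_", sc) else "")
        fit <- tryCatch(
          fit_before_after(
            tibble::tibble(year = series$year, value = series[[col]]),
            cfg$implementation_year, robust = cfg$robust,
            post_from = cfg$post_from
          ),
          error = function(e) {
            note("%s: fit skipped (%s)", nm, conditionMessage(e))
            NULL
          }
        )
        if (is.null(fit)) next
        fits[[nm]] <- fit
        effects[[nm]] <- tibble::tibble(
          indicator = measure, taxon = NA_character_, scope = sc, fit$effect
        )
      }
    }
  }

  governance <- if (!is.null(cfg$governance)) read_governance(cfg$governance) else NULL
  rubric <- governance_rubric(cfg$rubric)

  effects_tbl <- dplyr::bind_rows(effects)
  undefined <- effects_tbl[is.na(effects_tbl$beta), ]
  if (nrow(undefined) > 0) {
    note("unscored (undefined effect): %s", paste(undefined$indicator, collapse = ", "))
  }
  scorecard <- build_scorecard(effects_tbl, governance = governance,
                               rubric = rubric, scoring = cfg$scoring)

  artifacts <- render_report(scorecard, fits = fits,
                             config = cfg$reserve, dir = cfg$output_dir,
                             indicator_table = indicator_table,
                             plots = isTRUE(cfg$plots))
  writeLines(log, file.path(cfg$output_dir, "run.log"))
  artifacts$log <- file.path(cfg$output_dir, "run.log")

  list(status = 0L, design = design, scorecard = scorecard, fits = fits,
       indicator_table = indicator_table, artifacts = artifacts, log = log)
}

load_run_config <- function(config, ...) {
  if (is.character(config) && length(config) == 1) {
    base_dir <- dirname(config)
    cfg <- yaml::read_yaml(config)
    for (f in c("surveys", "traits", "econ", "cpi", "governance", "rubric")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        cfg[[f]] <- file.path(base_dir, cfg[[f]])
      }
    }
  } else {
    cfg <- config
  }
  cfg <- modifyList(cfg, list(...))

  defaults <- list(robust = "HC1", post_from = "impl-year", scoring = "sign",
                   deflation = "as-printed", min_transects = 12,
                   allow_design_failure = FALSE, output_dir = "results",
                   plots = TRUE, target_species = character(),
                   exclude_species = character(), reserve_name = "reserve")
  cfg <- modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  cfg$target_species <- as.character(unlist(cfg$target_species))
  cfg$exclude_species <- as.character(unlist(cfg$exclude_species))

  if (is.null(cfg$surveys)) stop("config must provide a 'surveys' path")
  if (is.null(cfg$implementation_year)) stop("config must provide 'implementation_year'")
  if (is.null(cfg$objectives)) stop("config must provide 'objectives'")
  if (!cfg$robust %in% c("HC0", "HC1", "HC2", "HC3")) {
    stop("robust must be one of HC0, HC1, HC2, HC3")
  }
  if (!cfg$post_from %in% c("impl-year", "impl-year+1")) {
    stop("post_from must be 'impl-year' or 'impl-year+1'")
  }
  if (!cfg$scoring %in% c("sign", "strict")) stop("scoring must be 'sign' or 'strict'")
  if (!cfg$deflation %in% c("as-printed", "standard")) {
    stop("deflation must be 'as-printed' or 'standard'")
  }
  cfg$implementation_year <- as.integer(cfg$implementation_year)
  cfg$objectives <- normalize_objectives(unlist(cfg$objectives))
  cfg$reserve <- reserve_config(
    reserve_name = cfg$reserve_name,
    implementation_year = cfg$implementation_year,
    objectives = cfg$objectives,
    target_species = cfg$target_species,
    exclude_species = cfg$exclude_species
  )
  cfg
}
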