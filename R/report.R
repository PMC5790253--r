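#' Render the scorecard and technical report
#'
#' Writes the evaluation artifacts to a directory: `scorecard.json`
#' (machine-readable, keys `global`, `categories`, `indicators`,
#' `passthrough`), `report.md` (human-readable technical report with the
#' scorecard, regression tables with robust standard errors and R², and the
#' governance narratives), `coefficients.csv` (one tidy row per coefficient
#' per fitted model), and — when an indicator table is supplied — one
#' time-series plot per indicator showing every transect value (jittered)
#' with the yearly mean ± 1 standard error per zone.
#'
#' Regenerating the report from the same inputs produces identical numeric
#' artifacts; only the timestamp line changes.
#'
#' @param scorecard A `reserve_scorecard` from [build_scorecard()].
#' @param fits Named list of `reserve_fit` objects (names label the rows of
#'   the coefficient table).
#' @param config Optional [reserve_config()] (adds reserve metadata to the
#'   report header).
#' @param dir Output directory, created if needed.
#' @param indicator_table Optional output of [compute_indicator_table()]
#'   used to draw the per-indicator time-series figures.
#' @param plots Draw figures (PNG) when an indicator table is supplied.
#' @return Named list of artifact paths, invisibly.
#' @export
render_report <- function(scorecard, fits = list(), config = NULL,
                          dir = ".", indicator_table = NULL, plots = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(scorecard = file.path(dir, "scorecard.json"),
                report = file.path(dir, "report.md"),
                coefficients = file.path(dir, "coefficients.csv"))

  ind <- scorecard$indicators
  scorecard_json <- list(
    global = scorecard$global_score,
    scoring = scorecard$scoring,
    categories = as.list(scorecard$category_scores),
    indicators = ind,
    passthrough = scorecard$passthrough
  )
  jsonlite::write_json(scorecard_json, paths$scorecard, dataframe = "rows",
                       na = "null", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  if (length(fits) > 0) {
    readr::write_csv(coefficients_table(fits), paths$coefficients)
  }

  lines <- c(
    "# Marine reserve effectiveness report",
    "",
    if (!is.null(config)) sprintf("Reserve: **%s** (implemented %d)",
                                  config$reserve_name,
                                  config$implementation_year),
    sprintf("Generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "",
    "## Scorecard",
    "",
    sprintf("Global score: **%.0f%%** positive indicators (scoring mode: %s)",
            scorecard$global_score, scorecard$scoring),
    "",
    "| Category | Score |",
    "|---|---|",
    sprintf("| %s | %s |", names(scorecard$category_scores),
            ifelse(is.na(scorecard$category_scores), "-",
                   sprintf("%.0f%%", scorecard$category_scores))),
    "",
    "| Indicator | Taxon | Scope | Effect | p | Color |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s |",
            ind$code,
            ifelse(is.na(ind$taxon), "-", ind$taxon),
            ifelse(is.na(ind$scope), "-", ind$scope),
            ifelse(is.na(ind$beta), "-", sprintf("%.4g", ind$beta)),
            ifelse(is.na(ind$p), "-", sprintf("%.4f", ind$p)),
            ifelse(is.na(ind$color), "narrative", ind$color))
  )

  if (length(fits) > 0) {
    lines <- c(lines, "", "## Regression tables", "")
    for (nm in names(fits)) {
      f <- fits[[nm]]
      lines <- c(lines,
        sprintf("### %s", nm),
        "",
        sprintf("Model: %s; robust SE flavor %s; n = %d; R² = %.4f%s",
                f$model, f$robust, f$n, f$r_squared,
                if (identical(f$causal, FALSE)) "; before-after only, not causal" else ""),
        "",
        "| Term | Estimate | Robust SE | t | p |",
        "|---|---|---|---|---|",
        sprintf("| %s | %.6g | %.6g | %.4f | %.4f |",
                f$coefficients$term, f$coefficients$estimate,
                f$coefficients$robust_se, f$coefficients$t, f$coefficients$p),
        "")
    }
  }

  if (nrow(scorecard$passthrough) > 0) {
    lines <- c(lines, "## Governance narratives (not scored)", "",
               sprintf("- **%s**: %s", scorecard$passthrough$code,
                       scorecard$passthrough$value), "")
  }

  if (!is.null(indicator_table) && plots) {
    fig_dir <- file.path(dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    paths$figures <- plot_indicator_series(indicator_table, fig_dir)
    lines <- c(lines, "## Figures", "",
               sprintf("- `%s`", file.path("figures", basename(paths$figures))))
  }

  writeLines(lines, paths$report)
  invisible(paths)
}

#' Per-indicator time-series plots
#'
#' One figure per (indicator, taxon, scope): transect values as jittered
#' points colored by zone, with the yearly mean and a ribbon of ± 1
#' standard error per zone.
#'
#' @param indicator_table Output of [compute_indicator_table()].
#' @param dir Directory for the PNG files.
#' @return Character vector of file paths, invisibly.
#' @export
plot_indicator_series <- function(indicator_table, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- dplyr::group_split(
    dplyr::group_by(indicator_table, .data$indicator, .data$taxon, .data$scope)
  )
  files <- vapply(groups, function(df) {
    df <- df[!is.na(df$value), ]
    slug <- paste(df$indicator[1], df$taxon[1],
                  gsub("[^A-Za-z0-9]", "_", df$scope[1]), sep = "_")
    file <- file.path(dir, paste0(slug, ".png"))
    if (nrow(df) == 0) return(file)
    summ <- dplyr::summarise(
      dplyr::group_by(df, .data$zone, .data$year),
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value,
                                           color = .data$zone)) +
      ggplot2::geom_point(
        position = ggplot2::position_jitter(width = 0.15, height = 0, seed = 1),
        alpha = 0.4, size = 0.8
      ) +
      ggplot2::geom_ribbon(
        data = summ,
        ggplot2::aes(x = .data$year, ymin = .data$mean - .data$se,
                     ymax = .data$mean + .data$se, fill = .data$zone),
        inherit.aes = FALSE, alpha = 0.25
      ) +
      ggplot2::geom_line(
        data = summ,
        ggplot2::aes(x = .data$year, y = .data$mean, color = .data$zone),
        linewidth = 0.8
      ) +
      ggplot2::scale_color_manual(values = c(control = "#4575b4", reserve = "#d73027"),
                                  aesthetics = c("colour", "fill")) +
      ggplot2::labs(
        title = sprintf("%s (%s%s)",
                        INDICATOR_LABELS[df$indicator[1]], df$taxon[1],
                        if (identical(df$scope[1], "all")) "" else paste0(", ", df$scope[1])),
        x = "Year", y = "Indicator value", color = "Zone", fill = "Zone"
      ) +
      ggplot2::theme_minimal()
    suppressWarnings(ggplot2::ggsave(file, gg, width = 6, height = 4, dpi = 120))
    file
  }, character(1))
  invisible(files)
}
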