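#' Canonical management objectives
#'
#' The seven management objectives a no-take reserve is commonly created
#' for. Objectives are referenced by key or full name throughout.
#'
#' @return A tibble (`key`, `name`).
#' @export
reserve_objectives <- function() {
  tibble::tibble(
    key = c("avoid_overexploitation", "conserve_protected_species",
            "maintain_biological_processes", "improve_fishery_production",
            "preserve_biodiversity", "recover_overexploited_species",
            "recover_economic_species"),
    name = c(
      "Avoid overexploitation",
      "Conserve species under a special protection regime",
      "Maintain biological processes (reproduction, recruitment, growth, feeding)",
      "Improve fishery production in adjacent waters",
      "Preserve biological diversity and the ecosystem",
      "Recover overexploited species",
      "Recover species of economic interest"
    )
  )
}

# objective -> indicator matrix; entries with a trailing * are the
# target-species variants of an indicator
OBJECTIVE_INDICATORS <- list(
  avoid_overexploitation = c("B3", "B4", "B4*", "B5", "B6", "B7", "B7*",
                             "S1", "S1*", "S2", "S2*", "S3"),
  conserve_protected_species = c("B3", "B4*", "B5", "B7*", "S1", "S2", "S3"),
  maintain_biological_processes = c("B1", "B2", "B4", "B5", "B6", "B7", "S3"),
  improve_fishery_production = c("B4", "B4*", "B5", "B7", "B7*",
                                 "S1", "S1*", "S2", "S2*", "S3"),
  preserve_biodiversity = c("B1", "B2", "B4", "B5", "B6", "B7", "S3"),
  recover_overexploited_species = c("B3", "B4*", "B5", "B7*", "S1*", "S2*", "S3"),
  recover_economic_species = c("B3", "B4*", "B5", "B7*", "S1*", "S2*", "S3")
)

normalize_objectives <- function(objectives) {
  tab <- reserve_objectives()
  keys <- character(length(objectives))
  for (i in seq_along(objectives)) {
    ob <- objectives[[i]]
    hit <- which(tab$key == ob | tolower(tab$name) == tolower(ob) |
                   startsWith(tolower(tab$name), tolower(ob)))
    if (length(hit) != 1) {
      stop("unknown or ambiguous objective: '", ob, "'; see reserve_objectives()")
    }
    keys[i] <- tab$key[hit]
  }
  unique(keys)
}

#' Match management objectives to performance indicators
#'
#' Returns the union of the indicator selections of the requested
#' objectives, including target-species variants (marked with a trailing
#' `*`), plus all governance indicators — every governance indicator is a
#' plausible explanatory variable for any objective. Users may deselect
#' indicators from the result afterwards.
#'
#' @param objectives Character vector of objective keys or full names.
#' @return Sorted character vector of indicator codes (e.g. `"B4"`,
#'   `"B4*"`, `"S1"`, `"G5"`).
#' @export
indicators_for_objectives <- function(objectives) {
  if (length(objectives) == 0) stop("at least one objective must be selected")
  keys <- normalize_objectives(objectives)
  codes <- unique(unlist(OBJECTIVE_INDICATORS[keys], use.names = FALSE))
  sort(unique(c(codes, paste0("G", 1:15))))
}

#' Color-code a numeric effect estimate
#'
#' The direction of change is the sign of the effect coefficient (the
#' interaction \eqn{\beta_2} for biological indicators, the before-after
#' slope \eqn{\beta_1} for economic ones): red for negative, green for
#' positive. Color intensity encodes the significance band of the
#' Student-t test of no change, with cutoffs p < 0.05 (strong, dark shade)
#' and p < 0.1 (weak). A coefficient that is not significant at p < 0.1 is
#' yellow regardless of its sign, as is an exactly zero coefficient.
#'
#' @param beta Effect estimate(s).
#' @param p Two-sided p-value(s) in \[0, 1\].
#' @return A tibble (`direction`, `intensity`, `color`); `NA` inputs yield
#'   `NA` rows (unscored).
#' @export
color_for <- function(beta, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  n <- max(length(beta), length(p))
  beta <- rep_len(beta, n)
  p <- rep_len(p, n)
  direction <- ifelse(beta > 0, "positive", ifelse(beta < 0, "negative", "neutral"))
  intensity <- ifelse(p < 0.05, "strong", ifelse(p < 0.1, "weak", "none"))
  color <- rep(NA_character_, n)
  ok <- !is.na(beta) & !is.na(p)
  color[ok] <- "yellow"
  color[ok & direction == "positive" & intensity == "weak"] <- "green"
  color[ok & direction == "positive" & intensity == "strong"] <- "dark_green"
  color[ok & direction == "negative" & intensity == "weak"] <- "red"
  color[ok & direction == "negative" & intensity == "strong"] <- "dark_red"
  direction[!ok] <- NA_character_
  intensity[!ok] <- NA_character_
  tibble::tibble(direction = direction, intensity = intensity, color = color)
}

#' The governance scoring rubric
#'
#' Governance responses are not analyzed statistically; each scorable code
#' is looked up in a rubric that records which response levels the
#' marine-governance literature regards as a negative (red) or positive
#' (green) factor for a reserve. Descriptive codes (reserve type,
#' enforcement description, reasoning for location, natural disturbance)
#' carry a narrative and pass through to the report unscored.
#'
#' The rubric ships as an editable CSV
#' (`system.file("extdata", "governance_rubric_synthetic.csv", package =
#' "mpaeval")`). It is a reconstruction written for this package from
#' published summaries of such rubrics — not a copy of any original scoring
#' table — and every row carries a note stating the reasoning; users with a
#' locally validated rubric should supply their own.
#'
#' @param path Optional path to a user-edited rubric CSV.
#' @return A tibble (`code`, `indicator`, `response_type`, `level`,
#'   `color`, `note`).
#' @export
governance_rubric <- function(path = NULL) {
  path <- path %||% system.file("extdata", "governance_rubric_synthetic.csv",
                                package = "mpaeval")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("code", "indicator", "response_type", "level", "color"),
                  path)
  tibble::as_tibble(df)
}

#' Score a governance response against the rubric
#'
#' @param code Governance code (`G1`–`G15`, `B5`, `S3`).
#' @param value Response level (case-insensitive).
#' @param rubric Rubric table from [governance_rubric()].
#' @return `"red"` or `"green"` for scorable codes; `NA_character_` for
#'   descriptive pass-through codes. An unknown level for a scorable code
#'   is an error listing the allowed levels.
#' @export
governance_color <- function(code, value, rubric = governance_rubric()) {
  code <- toupper(code)
  rows <- rubric[rubric$code == code, ]
  if (nrow(rows) == 0) {
    abort_validation(sprintf("governance code %s is not in the rubric", code))
  }
  if (all(rows$response_type == "descriptive")) return(NA_character_)
  lev <- tolower(trimws(as.character(value)))
  hit <- which(tolower(rows$level) == lev)
  if (length(hit) == 0) {
    abort_validation(sprintf(
      "unknown level '%s' for %s; allowed levels: %s",
      value, code, paste(rows$level, collapse = ", ")
    ))
  }
  rows$color[hit[1]]
}

#' Build the effectiveness scorecard
#'
#' Combines numeric effect estimates and governance responses into the
#' color-coded scorecard. Each numeric indicator gets a direction, a
#' significance intensity and a color via [color_for()]; governance
#' responses are scored red/green via [governance_color()]. Category scores
#' (biological, socioeconomic, governance) and the global score are the
#' percentage of positive indicators among the scored ones in their scope —
#' undefined or pass-through indicators are excluded from denominators.
#'
#' Two definitions of "positive" are available. The default (`"sign"`)
#' counts any indicator whose effect direction is positive, regardless of
#' significance (a yellow indicator with a positive coefficient counts).
#' `"strict"` only counts positives that are at least weakly significant
#' (p < 0.1).
#'
#' @param effects Tibble of numeric effect estimates with columns
#'   `indicator`, `beta`, `p` and optionally `taxon`, `scope`, `n`,
#'   `r_squared`, `model`.
#' @param governance Optional tibble of governance responses (`code`,
#'   `value`, `narrative`).
#' @param rubric Governance rubric ([governance_rubric()]).
#' @param scoring `"sign"` or `"strict"`.
#' @return A `reserve_scorecard` list: `indicators` (per-indicator tibble
#'   with colors and positivity), `category_scores`, `global_score`,
#'   `passthrough` (descriptive governance rows), `scoring`.
#' @export
build_scorecard <- function(effects, governance = NULL,
                            rubric = governance_rubric(),
                            scoring = c("sign", "strict")) {
  scoring <- match.arg(scoring)
  rows <- list()

  if (!is.null(effects) && nrow(effects) > 0) {
    effects <- tibble::as_tibble(effects)
    require_columns(effects, c("indicator", "beta", "p"), "effects table")
    if (!"taxon" %in% names(effects)) effects$taxon <- NA_character_
    if (!"scope" %in% names(effects)) effects$scope <- "all"
    cc <- color_for(effects$beta, effects$p)
    num <- tibble::tibble(
      code = effects$indicator, taxon = effects$taxon, scope = effects$scope,
      category = category_of(effects$indicator),
      beta = effects$beta, p = effects$p,
      direction = cc$direction, intensity = cc$intensity, color = cc$color,
      scored = !is.na(cc$color),
      positive = dplyr::case_when(
        is.na(cc$color) ~ NA,
        scoring == "sign" ~ cc$direction == "positive",
        TRUE ~ cc$direction == "positive" & cc$intensity %in% c("strong", "weak")
      )
    )
    rows <- c(rows, list(num))
  }

  passthrough <- tibble::tibble(code = character(), value = character(),
                                narrative = character())
  if (!is.null(governance) && nrow(governance) > 0) {
    governance <- tibble::as_tibble(governance)
    require_columns(governance, c("code", "value"), "governance table")
    if (!"narrative" %in% names(governance)) governance$narrative <- NA_character_
    col <- vapply(seq_len(nrow(governance)), function(i) {
      governance_color(governance$code[i], governance$value[i], rubric)
    }, character(1))
    gov <- tibble::tibble(
      code = toupper(governance$code), taxon = NA_character_, scope = "all",
      category = category_of(governance$code),
      beta = NA_real_, p = NA_real_,
      direction = ifelse(is.na(col), NA_character_,
                         ifelse(col == "green", "positive", "negative")),
      intensity = NA_character_, color = col,
      scored = !is.na(col),
      positive = ifelse(is.na(col), NA, col == "green")
    )
    rows <- c(rows, list(gov))
    passthrough <- governance[is.na(col), c("code", "value", "narrative")]
  }

  if (length(rows) == 0) stop("nothing to score: no effects and no governance responses")
  ind <- dplyr::bind_rows(rows)
  if (!any(ind$scored)) stop("no scorable indicators (all undefined or pass-through)")

  pct <- function(df) {
    df <- df[df$scored, ]
    if (nrow(df) == 0) return(NA_real_)
    100 * sum(df$positive) / nrow(df)
  }
  cats <- c("biological", "socioeconomic", "governance")
  category_scores <- setNames(
    vapply(cats, function(ct) pct(ind[ind$category == ct, ]), numeric(1)), cats
  )

  structure(list(
    indicators = ind,
    category_scores = category_scores,
    global_score = pct(ind),
    passthrough = passthrough,
    scoring = scoring
  ), class = "reserve_scorecard")
}

#' @export
print.reserve_scorecard <- function(x, ...) {
  cat(sprintf("Reserve effectiveness scorecard (global score %.0f%% positive, scoring = %s)\n",
              x$global_score, x$scoring))
  for (ct in names(x$category_scores)) {
    s <- x$category_scores[[ct]]
    cat(sprintf("  %-13s %s\n", ct,
                if (is.na(s)) "no scored indicators" else sprintf("%.0f%%", s)))
  }
  scored <- x$indicators[x$indicators$scored, ]
  lab <- ifelse(scored$scope == "all" | is.na(scored$scope),
                scored$code, paste0(scored$code, "[", scored$scope, "]"))
  lab <- ifelse(is.na(scored$taxon), lab, paste0(lab, " (", scored$taxon, ")"))
  cat("  indicators: ", paste(paste0(lab, "=", scored$color), collapse = ", "),
      "\n", sep = "")
  if (nrow(x$passthrough) > 0) {
    cat("  narrative pass-through:", paste(x$passthrough$code, collapse = ", "), "\n")
  }
  invisible(x)
}

category_of <- function(code) {
  first <- toupper(substr(code, 1, 1))
  c(B = "biological", S = "socioeconomic", G = "governance")[first]
}
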