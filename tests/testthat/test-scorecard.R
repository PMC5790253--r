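test_that("objectives map to their indicator sets plus all governance codes", {
  got <- indicators_for_objectives("Preserve biological diversity and the ecosystem")
  expect_setequal(got, c("B1", "B2", "B4", "B5", "B6", "B7", "S3",
                         paste0("G", 1:15)))

  all7 <- indicators_for_objectives(reserve_objectives()$key)
  expect_setequal(all7, c("B1", "B2", "B3", "B4", "B4*", "B5", "B6", "B7",
                          "B7*", "S1", "S1*", "S2", "S2*", "S3",
                          paste0("G", 1:15)))

  expect_error(indicators_for_objectives(character(0)), "objective")
  expect_error(indicators_for_objectives("win the lottery"), "unknown")
  # keys and full names are interchangeable
  expect_identical(indicators_for_objectives("preserve_biodiversity"), got)
})

test_that("color assignment matches the sign x significance-band legend exactly", {
  # exhaustive truth table over sign(beta) x p-band
  cases <- expand.grid(
    beta = c(-3, 0, 97.17),
    p = c(0.001, 0.049, 0.05, 0.07, 0.0999, 0.1, 0.5, 1),
    stringsAsFactors = FALSE
  )
  got <- color_for(cases$beta, cases$p)
  expected <- with(cases, ifelse(
    p >= 0.1 | beta == 0, "yellow",
    ifelse(beta > 0,
           ifelse(p < 0.05, "dark_green", "green"),
           ifelse(p < 0.05, "dark_red", "red"))
  ))
  expect_equal(got$color, expected)

  expect_equal(color_for(97.17, 0.02)$color, "dark_green")
  expect_equal(color_for(5.0, 0.50)$color, "yellow")
  expect_equal(color_for(-3.0, 0.03)$color, "dark_red")
  expect_error(color_for(1, 1.2), "0, 1")
  # undefined effects stay unscored
  expect_true(is.na(color_for(NA_real_, 0.01)$color))
})

test_that("governance responses score red/green or pass through per rubric", {
  expect_equal(governance_color("G5", "high"), "red")
  expect_equal(governance_color("G5", "low"), "green")
  expect_equal(governance_color("G10", "yes"), "green")
  expect_true(is.na(governance_color("G9", "local knowledge narrative")))
  expect_error(governance_color("G5", "rampant"), "allowed levels")
  expect_error(governance_color("G99", "x"), "not in the rubric")

  # every questionnaire code is either rubric-scored or explicit pass-through
  rubric <- governance_rubric()
  expect_setequal(unique(rubric$code), c(paste0("G", 1:15), "B5", "S3"))
  for (code in unique(rubric$code)) {
    rows <- rubric[rubric$code == code, ]
    expect_true(all(rows$response_type == "descriptive") ||
                  all(rows$color %in% c("red", "green")), label = code)
  }
})

test_that("category and global scores are percent positive among scored", {
  effects <- tibble::tibble(
    indicator = rep("B4", 10), taxon = "invertebrate",
    scope = paste0("sp", 1:10),
    beta = c(rep(1, 6), rep(-1, 4)), p = rep(0.01, 10)
  )
  sc <- build_scorecard(effects)
  expect_equal(sc$category_scores[["biological"]], 60)
  expect_equal(sc$global_score, 60)

  all_pos <- build_scorecard(dplyr::mutate(effects, beta = 2))
  expect_equal(all_pos$global_score, 100)

  # sign mode counts non-significant positives; strict mode does not
  mixed <- tibble::tibble(indicator = c("B4", "B4"), scope = c("a", "b"),
                          beta = c(3, 4), p = c(0.01, 0.8))
  expect_equal(build_scorecard(mixed, scoring = "sign")$global_score, 100)
  expect_equal(build_scorecard(mixed, scoring = "strict")$global_score, 50)

  # undefined indicators drop out of the denominator
  with_na <- dplyr::bind_rows(mixed, tibble::tibble(
    indicator = "B1", scope = "all", beta = NA_real_, p = NA_real_
  ))
  expect_equal(build_scorecard(with_na)$global_score, 100)
})

test_that("scores match a brute-force count on randomized scorecards and are order-invariant", {
  set.seed(99)
  for (i in 1:15) {
    n_num <- sample(3:12, 1)
    effects <- tibble::tibble(
      indicator = sample(c("B4", "B7", "S1", "S2"), n_num, TRUE),
      scope = paste0("s", seq_len(n_num)),
      beta = rnorm(n_num), p = runif(n_num)
    )
    gov <- tibble::tibble(
      code = sample(c("G3", "G5", "G6", "G10", "G13"), 3),
      value = c("yes", "high", "no")[c(1, 2, 3)],
      narrative = NA_character_
    )
    gov$value <- vapply(gov$code, function(cd) {
      switch(cd, G5 = sample(c("low", "high"), 1), sample(c("yes", "no"), 1))
    }, character(1))
    sc <- build_scorecard(effects, governance = gov)

    expected_pos <- sum(effects$beta > 0) +
      sum(vapply(seq_len(nrow(gov)), function(i) {
        governance_color(gov$code[i], gov$value[i]) == "green"
      }, logical(1)))
    expect_equal(sc$global_score,
                 100 * expected_pos / (n_num + nrow(gov)),
                 tolerance = 1e-12)

    shuffled <- build_scorecard(effects[sample(n_num), ], governance = gov)
    expect_equal(shuffled$global_score, sc$global_score)
    expect_equal(shuffled$category_scores, sc$category_scores)
  }
})

test_that("removing a yellow indicator rescales scores but flips no color", {
  effects <- tibble::tibble(
    indicator = c("B4", "B7", "B1"), scope = c("a", "b", "c"),
    beta = c(2, -1, 0.5), p = c(0.01, 0.02, 0.5)
  )
  full <- build_scorecard(effects)
  drop_yellow <- build_scorecard(effects[effects$p < 0.1, ])
  shared <- intersect(paste(full$indicators$code, full$indicators$scope),
                      paste(drop_yellow$indicators$code, drop_yellow$indicators$scope))
  f <- full$indicators[paste(full$indicators$code, full$indicators$scope) %in% shared, ]
  d <- drop_yellow$indicators
  expect_equal(f$color, d$color)
  expect_equal(drop_yellow$global_score, 50)
  expect_equal(full$global_score, 100 * 2 / 3, tolerance = 1e-12)
})

test_that("report artifacts are complete, consistent and reproducible", {
  d <- did_2x2(5, 8, 10, 20, reps = 6, noise = 1)
  fit <- fit_did(d, 2001)
  effects <- tibble::tibble(indicator = "B4", taxon = "invertebrate",
                            scope = "all", fit$effect)
  gov <- tibble::tibble(code = c("G5", "G9"),
                        value = c("low", "sited by local knowledge"),
                        narrative = NA_character_)
  sc <- build_scorecard(effects, governance = gov)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  paths <- render_report(sc, fits = list(B4_invertebrate = fit), dir = dir1)
  render_report(sc, fits = list(B4_invertebrate = fit), dir = dir2)

  js <- jsonlite::fromJSON(paths$scorecard)
  expect_setequal(names(js),
                  c("global", "scoring", "categories", "indicators", "passthrough"))
  expect_equal(js$global, sc$global_score)

  coefs <- readr::read_csv(paths$coefficients, show_col_types = FALSE)
  expect_equal(nrow(coefs), ncol(fit$design$X))  # one row per design column

  expect_identical(readLines(paths$scorecard),
                   readLines(file.path(dir2, "scorecard.json")))
  strip_ts <- function(f) grep("^Generated:", readLines(f), value = TRUE,
                               invert = TRUE)
  expect_identical(strip_ts(paths$report),
                   strip_ts(file.path(dir2, "report.md")))
})
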