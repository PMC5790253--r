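test_that("Shannon index matches direct summation and its bounds", {
  expect_equal(shannon_index(c(A = 10, B = 10)), log(2))
  expect_equal(shannon_index(c(A = 7)), 0)
  # direct-summation oracle over p = 1/6, 1/3, 1/2
  p <- c(1, 2, 3) / 6
  expect_equal(shannon_index(c(A = 1, B = 2, C = 3)), -sum(p * log(p)),
               tolerance = 1e-12)
  expect_warning(h <- shannon_index(c(NONE = 0)), "undefined")
  expect_true(is.na(h))

  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    counts <- setNames(rpois(n, 8) + 1, letters[1:n])
    h <- shannon_index(counts)
    expect_gte(h, 0)
    expect_lte(h, log(species_richness(counts)) + 1e-12)
  }
})

test_that("richness and density count what was observed", {
  expect_equal(species_richness(c(A = 1, B = 2, C = 3)), 3)
  expect_equal(species_richness(c(NONE = 0)), 0)
  expect_equal(species_richness(c(A = 100)), 1)

  expect_equal(total_density(c(A = 4, B = 6)), 10)
  expect_equal(total_density(c(A = 4, B = 6), scope = "A"), 4)
  expect_equal(total_density(c(NONE = 0)), 0)

  # total density over all species equals the sum of single-species scopes
  set.seed(7)
  counts <- setNames(rpois(5, 10) + 1, letters[1:5])
  expect_equal(total_density(counts),
               sum(vapply(names(counts), total_density, numeric(1),
                          counts = counts)))
})

test_that("mature fraction is a percent, tie-inclusive and monotone", {
  expect_equal(mature_fraction(c(10, 20, 30), 15), 100 * 2 / 3)
  expect_equal(mature_fraction(c(5, 6), 15), 0)
  expect_equal(mature_fraction(c(15, 20), 15), 100)  # tie counts as mature
  expect_true(is.na(mature_fraction(numeric(0), 15)))
  expect_error(mature_fraction(c(10, -2), 15), "non-negative")

  set.seed(11)
  lengths <- runif(30, 5, 40)
  cuts <- sort(runif(5, 5, 40))
  fr <- vapply(cuts, function(m) mature_fraction(lengths, m), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_true(all(fr >= 0 & fr <= 100))
})

test_that("mean trophic level is abundance-weighted over known species", {
  expect_equal(mean_trophic_level(c(A = 1, B = 1), c(A = 2, B = 4)), 3)
  expect_equal(mean_trophic_level(c(A = 3, B = 1), c(A = 2, B = 4)), 2.5)
  expect_equal(mean_trophic_level(c(A = 5), c(A = 3.2)), 3.2)
  expect_warning(
    tl <- mean_trophic_level(c(A = 2, B = 3), c(A = 3)), "B"
  )
  expect_equal(tl, 3)
  expect_true(is.na(suppressWarnings(mean_trophic_level(c(A = 1), c(X = 2)))))
})

test_that("biomass follows W = a L^b, additively, in kg", {
  traits <- tibble::tibble(species = c("A", "B"), lw_a = c(0.01, 0.02),
                           lw_b = c(3, 2.8))
  one <- tibble::tibble(species = "A", length_cm = 10)
  expect_equal(transect_biomass(one, traits), 0.01)  # 0.01 * 10^3 g = 10 g
  two <- tibble::tibble(species = "A", length_cm = c(10, 20))
  expect_equal(transect_biomass(two, traits), 0.09)  # (10 + 80) g
  expect_equal(transect_biomass(one[0, ], traits), 0)

  # additive over organisms, homogeneous of degree 1 in lw_a
  set.seed(3)
  obs <- tibble::tibble(species = sample(c("A", "B"), 12, TRUE),
                        length_cm = runif(12, 5, 30))
  total <- transect_biomass(obs, traits)
  parts <- vapply(seq_len(nrow(obs)), function(i) {
    transect_biomass(obs[i, ], traits)
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-12)
  traits2 <- traits
  traits2$lw_a <- traits$lw_a * 3
  expect_equal(transect_biomass(obs, traits2), 3 * total, tolerance = 1e-12)

  # missing length falls back to the species mean on the transect
  mix <- tibble::tibble(species = c("A", "A"), length_cm = c(10, NA))
  expect_equal(transect_biomass(mix, traits), 0.02)
  expect_true(is.na(suppressWarnings(
    transect_biomass(tibble::tibble(species = "Z", length_cm = 10), traits)
  )))
})

test_that("indicator table has one row per indicator-scope-transect", {
  recs <- toy_surveys(n_transects = 1, years = 2005)
  recs <- recs[recs$zone == "control", ]
  tab <- compute_indicator_table(recs, indicators = c("B2", "B4"))
  expect_equal(nrow(tab), 2)

  recs10 <- toy_surveys(n_transects = 5, years = c(2005, 2007))
  recs10 <- recs10[recs10$zone == "control", ]  # 10 transect units
  recs10$species[recs10$species == "A"] <- "snail"
  tab <- compute_indicator_table(recs10, indicators = "B4",
                                 target_species = "snail")
  expect_equal(nrow(tab), 20)
  expect_equal(sort(unique(tab$scope)), c("all", "snail"))

  expect_warning(
    tab <- compute_indicator_table(
      dplyr::mutate(recs, group = "fish", length_cm = 12),
      traits = NULL, indicators = "B7"
    ),
    "skipped"
  )
  expect_equal(nrow(tab), 0)
  expect_match(attr(tab, "skipped"), "B7", all = FALSE)
})

test_that("fish and invertebrate communities are summarized separately and agree with brute force", {
  spec <- simulation_spec(years = 2005:2008, implementation_year = 2007,
                          transects_per_site_year = 4)
  rec <- simulate_baci(spec, seed = 21)
  traits <- default_species_pool()
  tab <- suppressWarnings(compute_indicator_table(
    rec, traits = traits, target_species = "lobster"
  ))
  expect_setequal(unique(tab$taxon[tab$indicator == "B4"]),
                  c("fish", "invertebrate"))
  expect_setequal(unique(tab$taxon[tab$indicator %in% c("B3", "B6", "B7")]),
                  "fish")

  # brute-force re-computation over the raw records for every cell
  for (i in sample(nrow(tab), 40)) {
    row <- tab[i, ]
    sub <- rec[rec$site == row$site & rec$zone == row$zone &
                 rec$year == row$year & rec$transect == row$transect &
                 rec$group == row$taxon, ]
    counts <- tapply(sub$count, sub$species, sum)
    counts <- counts[names(counts) != "NONE" & counts > 0]
    expected <- switch(row$indicator,
      B1 = -sum((counts / sum(counts)) * log(counts / sum(counts))),
      B2 = length(counts),
      B4 = if (row$scope == "all") sum(counts) else
        sum(sub$count[sub$species == row$scope]),
      B3 = {
        mat <- traits$length_at_maturity_cm[match(sub$species, traits$species)]
        ok <- !is.na(sub$length_cm) & !is.na(mat)
        100 * sum(sub$count[ok] * (sub$length_cm[ok] >= mat[ok])) / sum(sub$count[ok])
      },
      B6 = {
        tl <- traits$trophic_level[match(names(counts), traits$species)]
        sum(counts * tl) / sum(counts)
      },
      B7 = {
        a <- traits$lw_a[match(sub$species, traits$species)]
        b <- traits$lw_b[match(sub$species, traits$species)]
        keep <- if (row$scope == "all") !is.na(a) else
          !is.na(a) & sub$species == row$scope
        sum(sub$count[keep] * a[keep] * sub$length_cm[keep]^b[keep],
            na.rm = TRUE) / 1000
      }
    )
    if (length(expected) == 0 || is.na(expected)) next
    expect_equal(row$value, as.numeric(expected), tolerance = 1e-10,
                 info = paste(row$indicator, row$scope, row$transect))
  }
})
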