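# Shared fixtures and independent oracles used across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small hand-written survey table: 2 zones x 2 years, n transects each
toy_surveys <- function(n_transects = 2, years = c(2005, 2007),
                        species = c("A", "B"), counts = c(3, 5)) {
  grid <- expand.grid(
    zone = c("control", "reserve"), year = years,
    transect = sprintf("T%02d", seq_len(n_transects)),
    species = species, stringsAsFactors = FALSE
  )
  tibble::tibble(
    site = paste0(grid$zone, "_site"), zone = grid$zone, year = grid$year,
    transect = grid$transect, group = "invertebrate", species = grid$species,
    count = rep_len(counts, nrow(grid)), length_cm = NA_real_,
    temperature = 18, visibility = 10, depth = 12
  )
}

# balanced 2-period x 2-zone indicator data with exact cell means
did_2x2 <- function(control_before, control_after, reserve_before,
                    reserve_after, reps = 3, noise = 0, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(zone = c("control", "reserve"), year = c(2000, 2001),
                       rep = seq_len(reps), stringsAsFactors = FALSE)
  means <- ifelse(cells$zone == "control",
                  ifelse(cells$year == 2000, control_before, control_after),
                  ifelse(cells$year == 2000, reserve_before, reserve_after))
  tibble::tibble(
    value = means + rnorm(nrow(cells), 0, noise),
    year = cells$year, zone = cells$zone
  )
}

# textbook difference-of-differences of group means
did_oracle <- function(data, implementation_year = 2001) {
  post <- data$year >= implementation_year
  res <- data$zone == "reserve"
  (mean(data$value[res & post]) - mean(data$value[res & !post])) -
    (mean(data$value[!res & post]) - mean(data$value[!res & !post]))
}

# brute-force sandwich covariance, written term by term and independent of
# the package's robust_vcov path
sandwich_oracle <- function(X, residuals, flavor = "HC0") {
  n <- nrow(X)
  k <- ncol(X)
  bread <- solve(t(X) %*% X)
  h <- diag(X %*% bread %*% t(X))
  w <- switch(flavor,
    HC0 = rep(1, n),
    HC1 = rep(n / (n - k), n),
    HC2 = 1 / (1 - h),
    HC3 = 1 / (1 - h)^2
  )
  meat <- matrix(0, k, k)
  for (i in seq_len(n)) {
    xi <- X[i, , drop = FALSE]
    meat <- meat + w[i] * residuals[i]^2 * (t(xi) %*% xi)
  }
  bread %*% meat %*% bread
}

# invertebrate-only species pool for fast simulation in calibration checks
invert_pool <- function() default_species_pool()[6:9, ]

# null BACI spec matching the recommended minimum monitoring design
null_spec <- function(transects = 12, noise_sd = 10) {
  simulation_spec(
    years = 2001:2010, implementation_year = 2006,
    transects_per_site_year = transects, species = invert_pool(),
    density_effect = c(fish = 0, invertebrate = 0),
    noise = list(model = "gaussian", sd = noise_sd)
  )
}

# one simulated replicate -> the DiD fit for the density indicator
simulate_density_fit <- function(spec, seed, robust = "HC1") {
  rec <- simulate_baci(spec, seed = seed)
  tab <- compute_indicator_table(rec, indicators = "B4")
  fit_did(tab, spec$implementation_year, robust = robust)
}

simulate_density_effect <- function(spec, seed, robust = "HC1") {
  simulate_density_fit(spec, seed, robust)$effect
}
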