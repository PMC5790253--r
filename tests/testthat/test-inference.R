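test_that("design matrix has exactly the specified columns", {
  d <- did_2x2(5, 8, 10, 20)
  d$temperature <- rnorm(nrow(d), 18)
  d$visibility <- rnorm(nrow(d), 10)
  d$depth <- rnorm(nrow(d), 12)
  X <- build_design_matrix(d, 2001)$X
  expect_equal(ncol(X), 7)  # intercept + 1 year dummy + Z + PxZ + 3 covariates
  expect_equal(colnames(X),
               c("(Intercept)", "year2001", "reserve", "post_x_reserve",
                 "temperature", "visibility", "depth"))
  expect_true(all(X[, "year2001"] %in% 0:1))
  expect_true(all(X[, "post_x_reserve"] == X[, "year2001"] * X[, "reserve"]))

  # 11 years x 2 zones: intercept + 10 year dummies + Z + PxZ + 3 covariates
  set.seed(5)
  grid <- expand.grid(year = 2006:2016, zone = c("control", "reserve"),
                      rep = 1:3, stringsAsFactors = FALSE)
  d11 <- tibble::tibble(value = rnorm(nrow(grid)), year = grid$year,
                        zone = grid$zone, temperature = rnorm(nrow(grid)),
                        visibility = rnorm(nrow(grid)),
                        depth = rnorm(nrow(grid)))
  expect_equal(ncol(build_design_matrix(d11, 2012)$X), 16)

  one_zone <- d[d$zone == "reserve", ]
  expect_error(build_design_matrix(one_zone, 2001), "zone",
               class = "mpaeval_design_error")
  one_year <- d[d$year == 2000, ]
  expect_error(build_design_matrix(one_year, 2001), "year",
               class = "mpaeval_design_error")
})

test_that("missing covariates drop listwise, with a covariate-free fallback", {
  d <- did_2x2(5, 8, 10, 20, reps = 10, noise = 1)
  d$temperature <- rnorm(nrow(d), 18)
  d$temperature[1:4] <- NA
  design <- build_design_matrix(d, 2001)
  expect_equal(design$n_dropped, 4)
  expect_equal(nrow(design$X), nrow(d) - 4)

  d$temperature[seq_len(ceiling(0.6 * nrow(d)))] <- NA
  expect_message(design <- build_design_matrix(d, 2001), "covariate-free")
  expect_equal(design$covariates_used, character(0))
  expect_equal(nrow(design$X), nrow(d))
})

test_that("OLS fit recovers exact structure on noiseless inputs", {
  d <- did_2x2(4, 4, 4, 4)
  fit <- ols_fit(build_design_matrix(d, 2001))
  expect_equal(unname(fit$estimates["(Intercept)"]), 4)
  expect_equal(unname(fit$estimates[-1]), rep(0, 3), tolerance = 1e-12)

  # y exactly linear in one covariate -> R^2 = 1
  d <- did_2x2(5, 8, 10, 20, reps = 6, noise = 2, seed = 9)
  d$temperature <- rnorm(nrow(d))
  d$value <- 2 + 3 * d$temperature
  fit <- fit_did(d, 2001)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # collinear column named in the error
  d2 <- did_2x2(5, 8, 10, 20, reps = 4, noise = 1)
  d2$temperature <- 1  # constant, collinear with intercept
  expect_error(ols_fit(build_design_matrix(d2, 2001)), "temperature",
               class = "mpaeval_design_error")
})

test_that("two-period two-zone fit reproduces the textbook DiD estimator", {
  d <- did_2x2(5, 8, 10, 20)
  fit <- fit_did(d, 2001)
  expect_equal(unname(fit$effect$beta), 7, tolerance = 1e-12)
  expect_equal(unname(fit$effect$beta), did_oracle(d), tolerance = 1e-12)

  for (seed in 1:25) {
    d <- did_2x2(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 50),
                 runif(1, 0, 50), reps = sample(3:8, 1), noise = 5,
                 seed = seed)
    beta2 <- did_effect(d, 2001)$beta
    expect_equal(beta2, did_oracle(d), tolerance = 1e-10)
  }
})

test_that("robust covariance matches the brute-force sandwich oracle", {
  set.seed(101)
  d <- did_2x2(5, 8, 10, 20, reps = 6, noise = 3)
  d$temperature <- rnorm(nrow(d), 18)
  design <- build_design_matrix(d, 2001)
  fit <- ols_fit(design)
  for (flavor in c("HC0", "HC1", "HC2", "HC3")) {
    expect_equal(
      unname(robust_vcov(fit, flavor)),
      unname(sandwich_oracle(design$X, fit$residuals, flavor)),
      tolerance = 1e-10, info = flavor
    )
  }
  # HC1 is HC0 scaled by n/(n-k)
  n <- fit$n
  k <- fit$rank
  expect_equal(robust_vcov(fit, "HC1"), robust_vcov(fit, "HC0") * n / (n - k),
               tolerance = 1e-12)
  # noiseless fit -> zero robust covariance
  d0 <- did_2x2(5, 8, 10, 20)
  fit0 <- fit_did(d0, 2001)
  expect_equal(max(abs(fit0$vcov_robust)), 0, tolerance = 1e-16)
  expect_error(robust_vcov(fit, "HC9"), "flavor")
})

test_that("t statistics and p-values follow the Student-t convention", {
  # printed worked-example ratios: estimate / robust SE at 4 decimals
  expect_equal(round(t_and_p(10344.85, 3982.20, 10)$t, 4), 2.5978)
  expect_equal(round(t_and_p(14372.85, 3634.64, 10)$t, 4), 3.9544)

  tp <- t_and_p(0, 2, 10)
  expect_equal(tp$t, 0)
  expect_equal(tp$p, 1)
  tp <- t_and_p(5, 0, 10)
  expect_equal(tp$t, Inf)
  expect_equal(tp$p, 0)
  tp <- t_and_p(1.5, 0.5, 8)
  expect_equal(tp$p, 2 * pt(3, df = 8, lower.tail = FALSE))
})

test_that("estimates are invariant to row order and transect relabeling", {
  spec <- null_spec(transects = 12)
  rec <- simulate_baci(spec, seed = 31)
  tab <- compute_indicator_table(rec, indicators = "B4")
  e1 <- did_effect(tab, 2006)

  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  e2 <- did_effect(shuffled, 2006)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)

  relabeled <- tab
  relabeled$transect <- paste0("X_", relabeled$transect)
  e3 <- did_effect(relabeled, 2006)
  expect_equal(e1$beta, e3$beta, tolerance = 1e-12)
})

test_that("before-after fit equals the difference of period means", {
  series <- tibble::tibble(year = 2001:2006, value = c(1, 2, 3, 4, 5, 6))
  eff <- before_after_effect(series, 2004)
  expect_equal(eff$beta, mean(c(4, 5, 6)) - mean(c(1, 2, 3)), tolerance = 1e-12)

  const <- tibble::tibble(year = 2001:2006, value = 5)
  expect_equal(before_after_effect(const, 2004)$beta, 0, tolerance = 1e-12)

  # any series whose period means differ by a given amount returns it exactly
  set.seed(17)
  v <- rnorm(8)
  v[5:8] <- v[5:8] - mean(v[5:8]) + mean(v[1:4]) + 64.20
  series <- tibble::tibble(year = 2001:2008, value = v)
  expect_equal(before_after_effect(series, 2005)$beta, 64.20, tolerance = 1e-10)

  fit <- fit_before_after(series, 2005)
  expect_false(fit$causal)
  expect_error(fit_before_after(series, 1990), "each side",
               class = "mpaeval_design_error")
})
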