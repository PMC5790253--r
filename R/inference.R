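#' Build the BACI difference-in-differences design matrix
#'
#' Encodes the regression
#' \deqn{I = \beta_0 + \sum_{t \ge 2} \gamma_t Y_t + \beta_1 Z + \beta_2 (P
#' \times Z) + \beta_3 T + \beta_4 V + \beta_5 D + \epsilon}
#' where the response is a per-transect indicator value, years enter as
#' factor dummies with the first year as reference, Z is the treatment dummy
#' (control = 0, reserve = 1), P the post-implementation dummy (before = 0,
#' after = 1), and T, V, D are bottom temperature, horizontal visibility and
#' survey depth. The P main effect is intentionally absent: the year dummies
#' span it, and the model is kept exactly in this form. The reserve effect
#' is the interaction coefficient \eqn{\beta_2} on `post_x_reserve`.
#'
#' Rows with a missing response are dropped; rows with missing covariates
#' are dropped listwise with their count recorded, unless more than half the
#' rows would be lost, in which case the model falls back to the
#' covariate-free specification (field covariate records are imperfect and
#' losing the majority of transects is worse than losing the adjustment).
#'
#' @param data Data frame with columns `value`, `year`, `zone`, and
#'   optionally `temperature`, `visibility`, `depth`.
#' @param implementation_year Reserve implementation year.
#' @param post_from `"impl-year"` if the implementation year counts as
#'   post-implementation, `"impl-year+1"` otherwise.
#' @param covariates Use environmental covariates when available.
#' @return A `did_design` list: model matrix `X` (including intercept),
#'   response `y`, the rows `data` actually used, `n_dropped`,
#'   `covariates_used`, and `effect_term = "post_x_reserve"`.
#' @export
build_design_matrix <- function(data, implementation_year,
                                post_from = c("impl-year", "impl-year+1"),
                                covariates = TRUE) {
  post_from <- match.arg(post_from)
  data <- tibble::as_tibble(data)
  require_columns(data, c("value", "year", "zone"), "indicator data")
  data <- data[!is.na(data$value), ]
  if (nrow(data) == 0) abort_design("no non-missing indicator values")

  years <- sort(unique(data$year))
  if (length(years) < 2) abort_design("need at least 2 survey years to fit the model")
  if (length(unique(data$zone)) < 2) {
    abort_design("need both control and reserve zones to fit the model")
  }

  covs <- character()
  n_dropped <- 0L
  if (covariates) {
    covs <- intersect(c("temperature", "visibility", "depth"), names(data))
    covs <- covs[vapply(covs, function(cv) !all(is.na(data[[cv]])), logical(1))]
    if (length(covs) > 0) {
      complete <- stats::complete.cases(data[, covs, drop = FALSE])
      if (mean(!complete) > 0.5) {
        message(sprintf(
          "%.0f%% of rows lack covariates; falling back to a covariate-free model",
          100 * mean(!complete)
        ))
        covs <- character()
      } else {
        n_dropped <- sum(!complete)
        data <- data[complete, ]
      }
    }
  }

  year_f <- factor(data$year, levels = years)
  X_year <- stats::model.matrix(~year_f)[, -1, drop = FALSE]
  colnames(X_year) <- paste0("year", years[-1])
  Z <- as.numeric(data$zone == "reserve")
  P <- as.numeric(is_post(data$year, implementation_year, post_from))
  X <- cbind(`(Intercept)` = 1, X_year, reserve = Z, post_x_reserve = P * Z)
  for (cv in covs) X <- cbind(X, setNames(list(data[[cv]]), cv)[[1]])
  if (length(covs) > 0) {
    colnames(X)[(ncol(X) - length(covs) + 1):ncol(X)] <- covs
  }

  structure(list(
    X = X, y = as.numeric(data$value), data = data,
    n_dropped = n_dropped, covariates_used = covs,
    implementation_year = as.integer(implementation_year),
    post_from = post_from, effect_term = "post_x_reserve"
  ), class = "did_design")
}

#' Ordinary least squares fit of a design
#'
#' Fits the design by OLS and reports classical summaries; robust standard
#' errors are attached by [robust_vcov()] / [fit_did()].
#'
#' @param design A `did_design` from [build_design_matrix()].
#' @return A `reserve_fit` list: the underlying `lm` object, coefficient
#'   estimates, residuals, `n`, `rank`, residual degrees of freedom and R².
#' @export
ols_fit <- function(design) {
  X <- design$X
  y <- design$y
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort_design(sprintf(
      "design matrix is rank deficient; collinear column%s: %s",
      if (length(aliased) > 1) "s" else "", paste(aliased, collapse = ", ")
    ))
  }
  if (nrow(X) <= ncol(X)) {
    abort_design(sprintf(
      "too few observations (%d) for %d model parameters", nrow(X), ncol(X)
    ))
  }
  dd <- as.data.frame(X[, -1, drop = FALSE])
  dd$.y <- y
  fit <- stats::lm(.y ~ ., data = dd)

  structure(list(
    lm = fit,
    model = "did",
    design = design,
    estimates = coef(fit),
    residuals = stats::residuals(fit),
    n = nrow(X),
    rank = qr_x$rank,
    df_residual = nrow(X) - qr_x$rank,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    effect_term = design$effect_term
  ), class = "reserve_fit")
}

#' Heteroskedasticity-robust (sandwich) covariance matrix
#'
#' The sandwich estimator
#' \eqn{(X'X)^{-1} X' \mathrm{diag}(w_i e_i^2) X (X'X)^{-1}} with the usual
#' finite-sample weights: HC0 \eqn{w_i = 1}; HC1 \eqn{n/(n-k)}; HC2
#' \eqn{1/(1-h_i)}; HC3 \eqn{1/(1-h_i)^2}, where \eqn{h_i} is the leverage.
#'
#' @param fit A `reserve_fit` (or plain `lm`) object.
#' @param flavor One of `"HC0"`, `"HC1"`, `"HC2"`, `"HC3"`.
#' @return The robust covariance matrix of the coefficient estimates
#'   (symmetric positive semidefinite).
#' @export
robust_vcov <- function(fit, flavor = "HC1") {
  if (!flavor %in% c("HC0", "HC1", "HC2", "HC3")) {
    stop("unknown robust-SE flavor: ", flavor, " (use HC0, HC1, HC2 or HC3)")
  }
  lm_fit <- if (inherits(fit, "reserve_fit")) fit$lm else fit
  # a residual-free fit (legitimate on exact data) makes summary.lm grumble
  withCallingHandlers(
    sandwich::vcovHC(lm_fit, type = flavor),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Student-t statistic and two-sided p-value
#'
#' @param estimate Coefficient estimate(s).
#' @param se Standard error(s); a zero standard error yields an infinite t
#'   statistic with p = 0 (the no-change null is rejected exactly).
#' @param df Residual degrees of freedom (n minus model rank).
#' @return A list with components `t` and `p`.
#' @export
t_and_p <- function(estimate, se, df) {
  if (any(se < 0, na.rm = TRUE)) abort_validation("standard errors must be >= 0")
  if (any(df <= 0)) abort_validation("degrees of freedom must be positive")
  t <- ifelse(se == 0, sign(estimate) * Inf, estimate / se)
  p <- ifelse(se == 0, ifelse(estimate == 0, 1, 0),
              2 * pt(abs(t), df = df, lower.tail = FALSE))
  list(t = t, p = p)
}

#' Fit the difference-in-differences model for one indicator
#'
#' Builds the BACI design ([build_design_matrix()]), estimates it by OLS,
#' and attaches heteroskedasticity-robust standard errors, t statistics and
#' two-sided p-values for every coefficient. The reserve effect is the
#' `post_x_reserve` interaction coefficient: the difference between the
#' temporal trends of the reserve and control sites.
#'
#' @inheritParams build_design_matrix
#' @param robust Robust-SE flavor passed to [robust_vcov()]. HC1 is the
#'   default small-sample convention; all four classical flavors are
#'   available.
#' @return A `reserve_fit` with a tidy `coefficients` tibble (`term`,
#'   `estimate`, `robust_se`, `t`, `p`) and an `effect` one-row tibble for
#'   the interaction coefficient.
#' @export
fit_did <- function(data, implementation_year, robust = "HC1",
                    post_from = c("impl-year", "impl-year+1"),
                    covariates = TRUE) {
  design <- build_design_matrix(data, implementation_year,
                                post_from = match.arg(post_from),
                                covariates = covariates)
  fit <- ols_fit(design)
  finish_fit(fit, robust, model = "did")
}

#' Reserve effect estimate from the difference-in-differences model
#'
#' @inheritParams fit_did
#' @return A one-row tibble: `model`, `term`, `beta`, `se`, `t`, `p`, `n`,
#'   `r_squared`.
#' @export
did_effect <- function(data, implementation_year, robust = "HC1",
                       post_from = c("impl-year", "impl-year+1"),
                       covariates = TRUE) {
  fit_did(data, implementation_year, robust = robust,
          post_from = match.arg(post_from), covariates = covariates)$effect
}

#' Fit the before-after mean-shift model for an annual series
#'
#' For economic series no control site exists, so the model reduces to
#' \eqn{I_t = \beta_0 + \beta_1 P_t + \epsilon_t}: \eqn{\beta_1} is
#' algebraically the difference between the post- and pre-implementation
#' means. Robust standard errors are retained for consistency with the
#' BACI model. This comparison does not support causal inference (there is
#' no control), and the fit is flagged accordingly.
#'
#' @param series Data frame with columns `year` and `value`.
#' @param implementation_year Reserve implementation year.
#' @inheritParams fit_did
#' @return A `reserve_fit` with `model = "before_after"` and
#'   `causal = FALSE`; the effect row carries \eqn{\beta_1}.
#' @export
fit_before_after <- function(series, implementation_year, robust = "HC1",
                             post_from = c("impl-year", "impl-year+1")) {
  post_from <- match.arg(post_from)
  series <- tibble::as_tibble(series)
  require_columns(series, c("year", "value"), "annual series")
  series <- series[!is.na(series$value), ]
  post <- as.numeric(is_post(series$year, implementation_year, post_from))
  if (!any(post == 0) || !any(post == 1)) {
    abort_design("need at least one year on each side of the implementation year")
  }
  X <- cbind(`(Intercept)` = 1, post = post)
  design <- structure(list(
    X = X, y = as.numeric(series$value),
    data = tibble::tibble(series, post = post),
    n_dropped = 0L, covariates_used = character(),
    implementation_year = as.integer(implementation_year),
    post_from = post_from, effect_term = "post"
  ), class = "did_design")
  fit <- ols_fit(design)
  fit <- finish_fit(fit, robust, model = "before_after")
  fit$causal <- FALSE
  fit
}

#' Before-after effect estimate for an annual series
#'
#' @inheritParams fit_before_after
#' @return A one-row tibble with `beta` equal to mean(after) - mean(before).
#' @export
before_after_effect <- function(series, implementation_year, robust = "HC1",
                                post_from = c("impl-year", "impl-year+1")) {
  fit_before_after(series, implementation_year, robust = robust,
                   post_from = match.arg(post_from))$effect
}

# attach robust inference and the tidy coefficient/effect tables
finish_fit <- function(fit, robust, model) {
  vc <- robust_vcov(fit, robust)
  se <- sqrt(diag(vc))
  tp <- t_and_p(unname(fit$estimates), unname(se), fit$df_residual)
  terms <- names(fit$estimates)
  terms[terms == "(Intercept)"] <- "(Intercept)"
  coefs <- tibble::tibble(
    term = terms, estimate = unname(fit$estimates),
    robust_se = unname(se), t = tp$t, p = tp$p
  )
  i <- which(coefs$term == fit$effect_term)
  fit$model <- model
  fit$robust <- robust
  fit$vcov_robust <- vc
  fit$coefficients <- coefs
  fit$effect <- tibble::tibble(
    model = model, term = fit$effect_term,
    beta = coefs$estimate[i], se = coefs$robust_se[i],
    t = coefs$t[i], p = coefs$p[i],
    n = fit$n, r_squared = fit$r_squared
  )
  fit
}

#' @export
print.reserve_fit <- function(x, ...) {
  label <- switch(x$model,
    did = "BACI difference-in-differences fit (OLS, robust SEs)",
    before_after = "Before-after mean-shift fit (OLS, robust SEs)"
  )
  cat(label, sprintf("[%s]", x$robust), "\n")
  cat(sprintf("n = %d, residual df = %d, R^2 = %.4f\n",
              x$n, x$df_residual, x$r_squared))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  if (identical(x$causal, FALSE)) {
    cat("note: before-after comparison without a control site; not causal\n")
  }
  invisible(x)
}

#' Export tidy coefficient tables for a set of fits
#'
#' One row per coefficient per fit, in the layout of a technical-report
#' regression table.
#'
#' @param fits Named list of `reserve_fit` objects.
#' @return A tibble with `indicator`, `term`, `estimate`, `robust_se`, `t`,
#'   `p`, `n`, `r_squared`.
#' @export
coefficients_table <- function(fits) {
  dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(indicator = nm, f$coefficients, n = f$n, r_squared = f$r_squared)
  }))
}
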