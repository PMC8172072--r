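## Turn selected mu and sigma models into five-category BMI prevalence
## forecasts by age, sex and year, aggregated over a population table,
## with parameter-resampling uncertainty intervals.

#' Five-category BMI classification scheme
#'
#' Cut-points (kg/m2) define Underweight < 18.5, Healthy weight
#' 18.5-24.99, Overweight 25-29.99, Obese 30-34.99 and Very obese >= 35.
#' Intervals are left-closed (a BMI of exactly 25.0 is Overweight, 18.5 is
#' Healthy weight, 35.0 is Very obese). "At risk" means BMI >= 25:
#' Overweight, Obese or Very obese.
#'
#' @param cut_points strictly increasing numeric vector of four cut-points.
#' @return a `bmi_scheme` with `cut_points` and `labels`.
#' @export
bmi_category_scheme <- function(cut_points = c(18.5, 25, 30, 35)) {
  if (length(cut_points) != 4 || any(diff(cut_points) <= 0)) {
    abort_bmitraj("need 4 strictly increasing cut-points", "bmitraj_argument_error")
  }
  structure(
    list(
      cut_points = cut_points,
      labels = c("Underweight", "Healthy weight", "Overweight", "Obese",
                 "Very obese")
    ),
    class = "bmi_scheme"
  )
}

#' Predict (mu, sigma) from the two-step model pair
#'
#' Position first, then shape with the predicted position plugged in as
#' the `mu` covariate. A predicted sigma at or below zero (possible when a
#' polynomial shape model is extrapolated) is floored at `sigma_floor`
#' with a warning.
#'
#' @param mu_model,sigma_model fitted `bmi_fit` objects.
#' @param newdata covariates (`sex`, `age`, `year` or `year_c`).
#' @param sigma_floor small positive lower bound for sigma.
#' @return tibble: covariates plus `mu` and `sigma`.
#' @export
predict_mu_sigma <- function(mu_model, sigma_model, newdata, sigma_floor = 0.01) {
  nd <- model_frame(newdata)
  mu <- predict(mu_model, nd)
  nd$mu <- mu
  sigma <- predict(sigma_model, nd)
  if (any(sigma <= 0)) {
    rlang::warn(
      sprintf("%d predicted sigma value(s) <= 0 floored at %g",
              sum(sigma <= 0), sigma_floor),
      class = "bmitraj_sigma_floor"
    )
    sigma <- pmax(sigma, sigma_floor)
  }
  tibble::tibble(sex = nd$sex, age = nd$age,
                 year_c = nd$year_c, year = nd$year_c + 2003,
                 mu = mu, sigma = sigma)
}

#' Lognormal category prevalence
#'
#' Probabilities of the five BMI categories as lognormal CDF differences
#' at the scheme cut-points. Exact (no sampling); rows sum to 1.
#'
#' @param mu,sigma lognormal log-scale parameters (vectorised; sigma > 0).
#' @param scheme a [bmi_category_scheme()].
#' @return matrix with one row per (mu, sigma) and one labelled column per
#'   category.
#' @export
category_prevalence <- function(mu, sigma, scheme = bmi_category_scheme()) {
  if (any(sigma <= 0)) abort_bmitraj("sigma must be > 0", "bmitraj_domain_error")
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  cdf <- vapply(scheme$cut_points, function(q) plnorm(q, mu, sigma),
                numeric(n))
  if (!is.matrix(cdf)) cdf <- matrix(cdf, nrow = n)
  p <- cbind(cdf[, 1], cdf[, 2] - cdf[, 1], cdf[, 3] - cdf[, 2],
             cdf[, 4] - cdf[, 3], 1 - cdf[, 4])
  colnames(p) <- scheme$labels
  p
}

#' Proportion at increased risk (BMI >= 25)
#'
#' Sum of the Overweight, Obese and Very obese categories, i.e.
#' `1 - P(Underweight) - P(Healthy weight)`.
#'
#' @param prevalence a 5-probability vector or a matrix/data frame with
#'   the five category columns.
#' @return numeric vector.
#' @export
at_risk <- function(prevalence) {
  if (is.null(dim(prevalence))) {
    stopifnot(length(prevalence) == 5)
    return(sum(prevalence[3:5]))
  }
  p <- as.matrix(as.data.frame(prevalence)[,
         c("Overweight", "Obese", "Very obese")])
  rowSums(p)
}

check_population_coverage <- function(population, years, ages, sexes = 0:1) {
  need <- expand.grid(year = years, sex = sexes, age = ages)
  key <- paste(need$year, need$sex, need$age)
  have <- paste(population$year, population$sex, population$age)
  miss <- setdiff(key, have)
  if (length(miss)) {
    abort_bmitraj(
      sprintf("population table missing %d cell(s), e.g. (year sex age) = %s",
              length(miss), miss[1]),
      "bmitraj_coverage_error"
    )
  }
  if (anyDuplicated(have)) {
    abort_bmitraj("population table has duplicate (year, sex, age) keys",
                  "bmitraj_coverage_error")
  }
  invisible(population)
}

#' Default adult age grouping
#'
#' Eight groups: 18-24, 25-34, 35-44, 45-54, 55-64, 65-74, 75-84, 85+.
#'
#' @param age integer ages (>= 18).
#' @return factor of group labels.
#' @export
age_group <- function(age) {
  cut(age,
      breaks = c(18, 25, 35, 45, 55, 65, 75, 85, Inf), right = FALSE,
      labels = c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74",
                 "75-84", "85+"))
}

## population-weighted aggregation of single-age cells
aggregate_cells <- function(cells, population, require_coverage = TRUE) {
  if (require_coverage) {
    check_population_coverage(population, unique(cells$year), unique(cells$age),
                              sexes = unique(cells$sex))
  }
  labs <- bmi_category_scheme()$labels
  merged <- dplyr::inner_join(cells, population, by = c("year", "sex", "age"))
  merged$age_band <- as.character(age_group(merged$age))
  wmean <- function(df, grp) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        dplyr::across(dplyr::all_of(labs),
                      ~ sum(.x * .data$count) / sum(.data$count)),
        population = sum(.data$count), .groups = "drop"
      )
  }
  by_group <- wmean(merged, c("year", "sex", "age_band"))
  by_sex <- wmean(merged, c("year", "sex")) |>
    dplyr::mutate(age_band = "all")
  national <- wmean(merged, "year") |>
    dplyr::mutate(sex = NA_integer_, age_band = "all")
  out <- dplyr::bind_rows(by_group, by_sex, national)
  out$sex_label <- ifelse(is.na(out$sex), "all", sex_label(out$sex))
  out[, c("year", "sex", "sex_label", "age_band", labs, "population")]
}

#' Aggregate single-age prevalence over a population table
#'
#' Count-weighted mean prevalence per group: by sex and age group, by sex
#' (all ages), and national (both sexes, all ages), with weights taken
#' from the population counts of the matching year.
#'
#' @param cells tibble of single-age cells: `year`, `sex`, `age` and the
#'   five category columns.
#' @param population population table (`year`, `sex`, `age`, `count`)
#'   covering every aggregated cell.
#' @param require_coverage error when the population table misses a cell
#'   (default); with `FALSE`, uncovered cells are dropped from the
#'   weighted means (used when weighting by an observed sample whose
#'   sparse cells are legitimately empty).
#' @return tibble of aggregated rows (`age_band` = "all" marks sex-level
#'   and national rows; national rows have `sex_label` = "all").
#' @export
aggregate_prevalence <- function(cells, population, require_coverage = TRUE) {
  aggregate_cells(cells, population, require_coverage)
}

#' Project five-category BMI prevalence
#'
#' Evaluates the two-step model pair at every (year, sex, single age)
#' cell, converts to category prevalence via the lognormal CDF, and
#' aggregates over the population table. Deterministic. Years beyond the
#' declared extrapolation horizon raise a warning.
#'
#' @inheritParams predict_mu_sigma
#' @param years projection years.
#' @param ages single ages to evaluate (default 18:100).
#' @param population population table covering (years x sexes x ages).
#' @param scheme a [bmi_category_scheme()].
#' @param horizon latest year the projection is declared for.
#' @param require_coverage see [aggregate_prevalence()].
#' @return a `bmi_forecast`: aggregated tibble (see
#'   [aggregate_prevalence()]) with the single-age cells in
#'   `attr(, "cells")`.
#' @export
project_prevalence <- function(mu_model, sigma_model, years, ages = 18:100,
                               population, scheme = bmi_category_scheme(),
                               sigma_floor = 0.01, horizon = 2035,
                               require_coverage = TRUE) {
  if (any(years > horizon)) {
    rlang::warn(sprintf("projecting beyond the declared horizon (%d)", horizon))
  }
  grid <- expand.grid(year = as.integer(years), sex = 0:1,
                      age = as.integer(ages))
  ms <- predict_mu_sigma(mu_model, sigma_model, grid, sigma_floor = sigma_floor)
  p <- category_prevalence(ms$mu, ms$sigma, scheme)
  cells <- dplyr::bind_cols(
    tibble::as_tibble(grid), tibble::as_tibble(p),
    tibble::tibble(mu = ms$mu, sigma = ms$sigma)
  )
  agg <- aggregate_cells(cells, population, require_coverage)
  structure(agg, cells = cells, scheme = scheme,
            class = c("bmi_forecast", class(agg)))
}

repair_psd <- function(V) {
  eg <- eigen(V, symmetric = TRUE)
  if (all(eg$values >= 0)) return(V)
  rlang::warn("covariance not positive semi-definite; negative eigenvalues clipped")
  eg$vectors %*% diag(pmax(eg$values, 0), nrow(V)) %*% t(eg$vectors)
}

#' Uncertainty configuration for projections
#'
#' @param n_draws number of coefficient draws (>= 2).
#' @param seed RNG seed.
#' @param level interval level (0.95 for 95% intervals).
#' @return an `uncertainty_config` list.
#' @export
uncertainty_config <- function(n_draws = 1000, seed = 1L, level = 0.95) {
  check_number(n_draws, "n_draws", lower = 2)
  check_number(level, "level", lower = 0, upper = 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 level = level),
            class = "uncertainty_config")
}

#' Projection with parameter-resampling uncertainty intervals
#'
#' Draws coefficient vectors from a multivariate normal at each model's
#' estimates and covariance (mu and sigma models sampled independently;
#' their cross-covariance is not available from two separate fits),
#' recomputes the full aggregated projection per draw, and summarises each
#' aggregated cell by the draw mean and percentile interval. The plug-in
#' (deterministic) projection is reported alongside the draw mean.
#'
#' @inheritParams project_prevalence
#' @param ucfg an [uncertainty_config()].
#' @return long tibble: `year`, `sex_label`, `age_band`, `category`,
#'   `plugin`, `prevalence` (draw mean), `lower`, `upper`.
#' @export
project_uncertainty <- function(mu_model, sigma_model, years, ages = 18:100,
                                population, scheme = bmi_category_scheme(),
                                ucfg = uncertainty_config(),
                                sigma_floor = 0.01, horizon = 2035) {
  labs <- scheme$labels
  base <- withCallingHandlers(
    project_prevalence(mu_model, sigma_model, years, ages, population,
                       scheme, sigma_floor, horizon),
    bmitraj_sigma_floor = function(w) invokeRestart("muffleWarning")
  )
  key <- base[, c("year", "sex", "sex_label", "age_band")]
  n_cell <- nrow(key)
  draws <- array(NA_real_, dim = c(n_cell, length(labs), ucfg$n_draws))
  Vmu <- repair_psd(mu_model$vcov)
  Vsig <- repair_psd(sigma_model$vcov)
  withr::local_seed(ucfg$seed)
  mu_draws <- MASS::mvrnorm(ucfg$n_draws, mu_model$coefficients, Vmu)
  sig_draws <- MASS::mvrnorm(ucfg$n_draws, sigma_model$coefficients, Vsig)
  if (!is.matrix(mu_draws)) mu_draws <- matrix(mu_draws, nrow = ucfg$n_draws)
  if (!is.matrix(sig_draws)) sig_draws <- matrix(sig_draws, nrow = ucfg$n_draws)
  mu_d <- mu_model; sig_d <- sigma_model
  for (d in seq_len(ucfg$n_draws)) {
    mu_d$coefficients <- setNames(mu_draws[d, ], names(mu_model$coefficients))
    sig_d$coefficients <- setNames(sig_draws[d, ], names(sigma_model$coefficients))
    agg <- withCallingHandlers(
      project_prevalence(mu_d, sig_d, years, ages, population, scheme,
                         sigma_floor, horizon = Inf),
      bmitraj_sigma_floor = function(w) invokeRestart("muffleWarning")
    )
    draws[, , d] <- as.matrix(as.data.frame(agg)[, labs])
  }
  alpha <- (1 - ucfg$level) / 2
  out <- lapply(seq_along(labs), function(j) {
    m <- draws[, j, , drop = FALSE]
    dim(m) <- c(n_cell, ucfg$n_draws)
    tibble::tibble(
      year = key$year, sex = key$sex, sex_label = key$sex_label,
      age_band = key$age_band, category = labs[j],
      plugin = as.data.frame(base)[[labs[j]]],
      prevalence = rowMeans(m),
      lower = apply(m, 1, quantile, probs = alpha, names = FALSE),
      upper = apply(m, 1, quantile, probs = 1 - alpha, names = FALSE)
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$year, .data$sex_label, .data$age_band)
}

#' @rdname survey_csv
#' @param forecast a `bmi_forecast` or the tibble from
#'   [project_uncertainty()].
#' @export
write_forecast_csv <- function(forecast, path) {
  df <- as.data.frame(forecast)
  labs <- bmi_category_scheme()$labels
  if (all(labs %in% names(df))) {
    df <- tidyr::pivot_longer(df, dplyr::all_of(labs),
                              names_to = "category", values_to = "prevalence")
  }
  readr::write_csv(df, path)
  invisible(path)
}
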