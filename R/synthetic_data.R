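## Synthetic survey microdata with known lognormal trend surfaces.
##
## Every downstream stage (cohort construction, model selection,
## projection, validation) is testable by parameter recovery against the
## generating mu/sigma surfaces, without access to the original survey.

#' Configuration of the synthetic survey generator
#'
#' Defines the generating truth: per-year sample size, adult age range,
#' sex ratio, and coefficient surfaces for the position (`mu`) and shape
#' (`sigma`) of log-BMI. Surfaces are linear in the same term grammar as
#' the linear model family (intercept, sex, age, age2, year, year2 and
#' their interactions, year centred at 2003); the sigma surface may also
#' carry `mu` and `mu2` terms, evaluated at the generating mu. Defaults
#' reproduce the published optimal linear trend surfaces for England, with
#' 24 survey years and ~8,000 adults per year, so the default cohort
#' dataset lands at the scale of roughly 400 cohort-year rows.
#'
#' @param years integer survey years.
#' @param n_per_year adults sampled per survey year (>= 1).
#' @param age_range integer `c(min, max)` age in years, min >= 18.
#' @param sex_ratio proportion male in `[0, 1]` (sex coded 1 = male).
#' @param mu_truth named coefficients of the generating mu surface.
#' @param sigma_truth named coefficients of the generating sigma surface
#'   (may include `mu`, `mu2`).
#' @param seed mandatory RNG seed; identical config + seed gives
#'   byte-identical output.
#' @param age_sampler optional function `(n, age_range)` returning integer
#'   ages, plugged in when a non-uniform age structure is wanted; default
#'   samples ages uniformly to maximise covariate coverage.
#' @return a `generator_config` list.
#' @examples
#' cfg <- generator_config(years = 2000:2002, n_per_year = 100, seed = 1)
#' head(generate_survey(cfg))
#' @export
generator_config <- function(years = 1991:2014,
                             n_per_year = 8000,
                             age_range = c(18L, 95L),
                             sex_ratio = 0.5,
                             mu_truth = NULL,
                             sigma_truth = NULL,
                             seed,
                             age_sampler = NULL) {
  if (missing(seed)) abort_bmitraj("`seed` is mandatory", "bmitraj_argument_error")
  if (!length(years)) abort_bmitraj("`years` must be non-empty",
                                    "bmitraj_argument_error")
  check_number(n_per_year, "n_per_year", lower = 1)
  check_number(sex_ratio, "sex_ratio", lower = 0, upper = 1)
  if (length(age_range) != 2 || age_range[1] < 18 || age_range[2] < age_range[1]) {
    abort_bmitraj("`age_range` must be c(min, max) with min >= 18",
                  "bmitraj_argument_error")
  }
  if (is.null(mu_truth)) {
    rc <- reference_coefficients("mu", "linear")
    mu_truth <- setNames(rc$estimate, rc$term)
  }
  if (is.null(sigma_truth)) {
    rc <- reference_coefficients("sigma", "linear")
    sigma_truth <- setNames(rc$estimate, rc$term)
  }
  bad <- setdiff(names(mu_truth), setdiff(LINEAR_TERMS, c("mu", "mu2")))
  if (length(bad)) {
    abort_bmitraj(sprintf("mu_truth has unknown term(s): %s",
                          paste(bad, collapse = ", ")),
                  "bmitraj_config_error")
  }
  bad <- setdiff(names(sigma_truth), LINEAR_TERMS)
  if (length(bad)) {
    abort_bmitraj(sprintf("sigma_truth has unknown term(s): %s",
                          paste(bad, collapse = ", ")),
                  "bmitraj_config_error")
  }
  cfg <- structure(
    list(
      years = as.integer(years), n_per_year = as.integer(n_per_year),
      age_range = as.integer(age_range), sex_ratio = sex_ratio,
      mu_truth = mu_truth, sigma_truth = sigma_truth,
      seed = as.integer(seed), age_sampler = age_sampler
    ),
    class = "generator_config"
  )
  check_sigma_positive(cfg)
  cfg
}

eval_surface <- function(coefs, sex, age, year_c, mu = NULL) {
  df <- data.frame(sex = sex, age = age, year_c = year_c)
  if (!is.null(mu)) df$mu <- mu
  out <- numeric(nrow(df))
  for (t in names(coefs)) out <- out + coefs[[t]] * term_column(t, df)
  out
}

check_sigma_positive <- function(config) {
  grid <- expand.grid(
    sex = 0:1,
    age = seq(config$age_range[1], config$age_range[2]),
    year = config$years
  )
  ts <- truth_surface(config, grid$sex, grid$age, grid$year)
  if (any(ts$sigma <= 0)) {
    bad <- grid[ts$sigma <= 0, , drop = FALSE]
    abort_bmitraj(
      sprintf(
        "sigma surface is non-positive at %d covariate combination(s), e.g. sex=%d age=%d year=%d",
        nrow(bad), bad$sex[1], bad$age[1], bad$year[1]
      ),
      "bmitraj_config_error"
    )
  }
  invisible(config)
}

truth_surface <- function(config, sex, age, year) {
  year_c <- centre_year(year)
  mu <- eval_surface(config$mu_truth, sex, age, year_c)
  sigma <- eval_surface(config$sigma_truth, sex, age, year_c, mu = mu)
  list(mu = mu, sigma = sigma)
}

#' Generating (mu, sigma) at given covariates
#'
#' Oracle access to the exact lognormal parameters used by
#' [generate_survey()], for parameter-recovery tests.
#'
#' @param config a [generator_config()].
#' @param sex 0/1 vector.
#' @param age ages within the configured range.
#' @param year years within the configured set.
#' @return tibble with columns `sex`, `age`, `year`, `mu`, `sigma`.
#' @export
truth_parameters <- function(config, sex, age, year) {
  stopifnot(inherits(config, "generator_config"))
  n <- max(length(sex), length(age), length(year))
  sex <- rep_len(sex, n); age <- rep_len(age, n); year <- rep_len(year, n)
  if (!all(sex %in% 0:1)) abort_bmitraj("sex must be 0/1", "bmitraj_domain_error")
  if (any(age < config$age_range[1] | age > config$age_range[2])) {
    abort_bmitraj("age out of configured range", "bmitraj_domain_error")
  }
  if (!all(year %in% config$years)) {
    abort_bmitraj("year not in configured years", "bmitraj_domain_error")
  }
  ts <- truth_surface(config, sex, age, year)
  tibble::tibble(sex = sex, age = age, year = year, mu = ts$mu, sigma = ts$sigma)
}

#' Generate synthetic survey microdata
#'
#' For each configured year draws `n_per_year` adults: age uniform over
#' the configured range (unless an `age_sampler` is plugged in), sex
#' Bernoulli(`sex_ratio`), and BMI as
#' `exp(Normal(mu(sex, age, year), sigma(sex, age, year)))` from the
#' generating surfaces. Deterministic under the configured seed.
#'
#' @param config a [generator_config()].
#' @return tibble of survey records: `year`, `age`, `sex`, `bmi`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)
  n <- config$n_per_year
  sampler <- config$age_sampler %||%
    function(n, age_range) {
      ages <- seq(age_range[1], age_range[2])
      ages[sample.int(length(ages), n, replace = TRUE)]
    }
  rows <- lapply(config$years, function(y) {
    age <- as.integer(sampler(n, config$age_range))
    sex <- rbinom(n, 1L, config$sex_ratio)
    ts <- truth_surface(config, sex, age, rep(y, n))
    tibble::tibble(
      year = rep(as.integer(y), n), age = age, sex = sex,
      bmi = exp(rnorm(n, ts$mu, ts$sigma))
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic age/sex population projection table
#'
#' A stand-in for an official principal population projection: a smooth
#' adult age profile (slow decline in cell counts at older ages), a small
#' seeded perturbation per (sex, age) cell so the profile is not perfectly
#' smooth, and geometric growth across years. With `growth_rate = 0` the
#' age profile is identical in every year.
#'
#' @param years projection years (non-empty).
#' @param age_range integer `c(min, max)` ages.
#' @param growth_rate annual growth rate applied to all cells.
#' @param seed RNG seed for the cell perturbations.
#' @param base_count scale of a single-age single-sex cell count.
#' @return tibble `year`, `sex`, `age`, `count` with positive counts and
#'   one row per (year, sex, age).
#' @export
generate_population_weights <- function(years, age_range = c(18L, 95L),
                                        growth_rate = 0.005, seed = 1L,
                                        base_count = 350000) {
  if (!length(years)) abort_bmitraj("`years` must be non-empty",
                                    "bmitraj_argument_error")
  withr::local_seed(seed)
  ages <- seq(age_range[1], age_range[2])
  base <- expand.grid(sex = 0:1, age = ages)
  ## plateau through mid-life, tapering at older ages
  shape <- exp(-pmax(base$age - 55, 0)^2 / (2 * 18^2))
  noise <- exp(rnorm(nrow(base), 0, 0.02))
  base$count0 <- base_count * shape * noise * ifelse(base$sex == 0, 1.02, 0.98)
  out <- lapply(sort(as.integer(years)), function(y) {
    tibble::tibble(
      year = y, sex = base$sex, age = as.integer(base$age),
      count = base$count0 * (1 + growth_rate)^(y - min(years))
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$year, .data$sex, .data$age)
}

## ---- CSV interfaces ----------------------------------------------------

#' Write / read survey and population CSV files
#'
#' Survey CSV schema: `year,age,sex,bmi` (sex 1 = male / 0 = female, BMI in
#' kg/m2 written with 4 decimal places). Population CSV schema:
#' `year,sex,age,count`.
#'
#' @param records survey records tibble.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return tibbles.
#' @name survey_csv
#' @export
write_survey_csv <- function(records, path) {
  records$bmi <- round(records$bmi, 4)
  readr::write_csv(records[, c("year", "age", "sex", "bmi")], path)
  invisible(path)
}

#' @rdname survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), age = readr::col_integer(),
    sex = readr::col_integer(), bmi = readr::col_double()
  ))
  need <- c("year", "age", "sex", "bmi")
  if (!all(need %in% names(df))) {
    abort_bmitraj(sprintf("survey CSV must have header %s",
                          paste(need, collapse = ",")),
                  "bmitraj_schema_error")
  }
  df
}

#' @rdname survey_csv
#' @param population population table tibble.
#' @export
write_population_csv <- function(population, path) {
  readr::write_csv(population[, c("year", "sex", "age", "count")], path)
  invisible(path)
}

#' @rdname survey_csv
#' @export
read_population_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), sex = readr::col_integer(),
    age = readr::col_integer(), count = readr::col_double()
  ))
  need <- c("year", "sex", "age", "count")
  if (!all(need %in% names(df))) {
    abort_bmitraj(sprintf("population CSV must have header %s",
                          paste(need, collapse = ",")),
                  "bmitraj_schema_error")
  }
  df
}
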