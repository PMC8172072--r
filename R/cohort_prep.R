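## Survey record filtering, birth-cohort construction, and per-cell
## lognormal parameter estimation.

#' Filter survey records to plausible adult BMI values
#'
#' Keeps adults (`age >= age_min`) with BMI inside the inclusive bounds
#' `[bmi_min, bmi_max]`; implausibly low or high BMI values (data-entry
#' era artefacts in measurement surveys) are removed.
#'
#' @param records survey records (`year`, `age`, `sex`, `bmi`).
#' @param bmi_min,bmi_max inclusive BMI bounds in kg/m2.
#' @param age_min minimum adult age in years.
#' @return list with `records` (kept rows) and `removed_fraction`.
#' @export
filter_records <- function(records, bmi_min = 10, bmi_max = 65, age_min = 18) {
  if (!nrow(records)) abort_bmitraj("no records supplied", "bmitraj_empty_dataset")
  keep <- records$age >= age_min & records$bmi >= bmi_min & records$bmi <= bmi_max
  keep[is.na(keep)] <- FALSE
  kept <- records[keep, , drop = FALSE]
  if (!nrow(kept)) {
    abort_bmitraj("all records removed by filtering", "bmitraj_empty_dataset")
  }
  list(records = kept, removed_fraction = 1 - nrow(kept) / nrow(records))
}

#' Annotate records with ten-year birth cohorts
#'
#' Birth year is `year - age`; the cohort label is the birth decade,
#' `floor((year - age) / width) * width`, so the same individual-equivalent
#' (fixed `year - age`) maps to the same cohort in every survey year.
#'
#' @param records filtered survey records.
#' @param width cohort width in years (10-year birth cohorts by default).
#' @return records with a `cohort_label` column.
#' @export
assign_cohorts <- function(records, width = 10) {
  check_number(width, "width", lower = 1)
  records$cohort_label <- as.integer(floor((records$year - records$age) / width) * width)
  records
}

#' Closed-form lognormal fit
#'
#' Maximum-likelihood fit of a lognormal distribution: `mu_hat` is the
#' mean of the logs and `sigma_hat` the population (divisor `n`) standard
#' deviation of the logs.
#'
#' @param values positive numeric vector, length >= 2.
#' @return named vector `c(mu, sigma)`.
#' @export
fit_lognormal <- function(values) {
  if (length(values) < 2) {
    abort_bmitraj("need at least 2 values", "bmitraj_insufficient_data")
  }
  if (any(values <= 0)) {
    abort_bmitraj("lognormal fit requires positive values", "bmitraj_domain_error")
  }
  l <- log(values)
  mu <- mean(l)
  c(mu = mu, sigma = sqrt(mean((l - mu)^2)))
}

#' Compare lognormal, gamma and Weibull fits by KS statistic
#'
#' Fits the three candidate families by maximum likelihood
#' (via [fitdistrplus::fitdist()]) and ranks them by the
#' Kolmogorov-Smirnov statistic against the fitted distribution; the
#' winner has the lowest KS. A family whose fit fails is flagged unfit and
#' excluded from winner selection with a warning.
#'
#' @param values positive numeric vector, length >= 30.
#' @return list with `table` (tibble: `family`, `ks`, `fitted` parameter
#'   list, `ok`) and `winner`.
#' @export
compare_distributions <- function(values) {
  if (length(values) < 30) {
    abort_bmitraj("need at least 30 values", "bmitraj_insufficient_data")
  }
  if (any(values <= 0)) {
    abort_bmitraj("distribution comparison requires positive values",
                  "bmitraj_domain_error")
  }
  fams <- c(lognormal = "lnorm", gamma = "gamma", weibull = "weibull")
  rows <- lapply(names(fams), function(f) {
    fit <- tryCatch(
      suppressWarnings(fitdistrplus::fitdist(values, fams[[f]])),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      rlang::warn(sprintf("%s fit failed; excluded from comparison", f))
      return(tibble::tibble(family = f, ks = NA_real_,
                            fitted = list(NULL), ok = FALSE))
    }
    ks <- suppressWarnings(fitdistrplus::gofstat(fit))$ks
    tibble::tibble(family = f, ks = unname(ks),
                   fitted = list(as.list(fit$estimate)), ok = TRUE)
  })
  tab <- dplyr::bind_rows(rows)
  if (!any(tab$ok)) abort_bmitraj("all distribution fits failed",
                                  "bmitraj_fit_error")
  winner <- tab$family[tab$ok][which.min(tab$ks[tab$ok])]
  list(table = tab, winner = winner)
}

#' Squared skewness and kurtosis for distribution screening
#'
#' The coordinates of a Cullen-Frey diagnostic: squared sample skewness
#' and (non-excess) sample kurtosis, so a normal sample sits near (0, 3).
#'
#' @param values numeric vector, length >= 4, non-zero variance.
#' @return named vector `c(skewness_squared, kurtosis)`.
#' @export
cullen_frey <- function(values) {
  if (length(values) < 4) {
    abort_bmitraj("need at least 4 values", "bmitraj_insufficient_data")
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) abort_bmitraj("zero variance: moments undefined",
                             "bmitraj_domain_error")
  skew <- mean((values - m)^3) / m2^1.5
  kurt <- mean((values - m)^4) / m2^2
  c(skewness_squared = skew^2, kurtosis = kurt)
}

#' Build the cohort-parameter dataset
#'
#' Collapses filtered, cohort-annotated survey records into one row per
#' (birth cohort, survey year, sex) cell with at least `min_cell_n`
#' records: the cell's mean age, sample size, and closed-form lognormal
#' `mu_hat` / `sigma_hat` of its BMI values, with the centred year
#' (`year_c = year - 2003`). These rows are what the trend regressions
#' are fitted to.
#'
#' @param records filtered records carrying `cohort_label` (see
#'   [assign_cohorts()]).
#' @param min_cell_n minimum records per cell; smaller cells are dropped
#'   (their sigma_hat would be unstable).
#' @return tibble of cohort observations: `cohort_label`, `year`,
#'   `year_c`, `sex`, `mean_age`, `n`, `mu_hat`, `sigma_hat`.
#' @export
build_cohort_dataset <- function(records, min_cell_n = 50) {
  if (!("cohort_label" %in% names(records))) {
    abort_bmitraj("records lack `cohort_label`; run assign_cohorts() first",
                  "bmitraj_schema_error")
  }
  obs <- records |>
    dplyr::group_by(.data$cohort_label, .data$year, .data$sex) |>
    dplyr::summarise(
      mean_age = mean(.data$age),
      n = dplyr::n(),
      mu_hat = mean(log(.data$bmi)),
      sigma_hat = sqrt(mean((log(.data$bmi) - mean(log(.data$bmi)))^2)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_cell_n) |>
    dplyr::mutate(year_c = centre_year(.data$year)) |>
    dplyr::select("cohort_label", "year", "year_c", "sex", "mean_age",
                  "n", "mu_hat", "sigma_hat") |>
    dplyr::arrange(.data$year, .data$cohort_label, .data$sex)
  if (!nrow(obs)) {
    abort_bmitraj(
      sprintf("no (cohort, year, sex) cell reaches min_cell_n = %d", min_cell_n),
      "bmitraj_empty_dataset"
    )
  }
  obs
}

#' @rdname survey_csv
#' @param observations cohort observations from [build_cohort_dataset()].
#' @export
write_cohort_csv <- function(observations, path) {
  readr::write_csv(observations, path)
  invisible(path)
}

#' @rdname survey_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cohort_label = readr::col_integer(), year = readr::col_integer(),
    year_c = readr::col_double(), sex = readr::col_integer(),
    mean_age = readr::col_double(), n = readr::col_integer(),
    mu_hat = readr::col_double(), sigma_hat = readr::col_double()
  ))
}
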