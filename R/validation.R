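## Score forecasts against held-out survey years: predicted vs observed
## five-category prevalence across sex x age-group cells.

#' Observed category prevalence from survey records
#'
#' Per (year, sex, age group): the share of records in each BMI category.
#' Category intervals are left-closed (25.0 counts as Overweight). Cells
#' with no records are omitted (not zero-filled).
#'
#' @param records filtered survey records.
#' @param scheme a [bmi_category_scheme()].
#' @return long tibble: `year`, `sex`, `age_band`, `category`, `observed`,
#'   `n_cell`; within a cell the observed shares sum to 1.
#' @export
observed_category_prevalence <- function(records,
                                         scheme = bmi_category_scheme()) {
  if (!nrow(records)) abort_bmitraj("no records supplied", "bmitraj_empty_dataset")
  cat <- cut(records$bmi, breaks = c(-Inf, scheme$cut_points, Inf),
             right = FALSE, labels = scheme$labels)
  df <- tibble::tibble(
    year = records$year, sex = records$sex,
    age_band = as.character(age_group(records$age)), category = as.character(cat)
  )
  counts <- df |>
    dplyr::count(.data$year, .data$sex, .data$age_band, .data$category)
  ## complete categories within observed cells only
  cells <- counts |>
    dplyr::group_by(.data$year, .data$sex, .data$age_band) |>
    dplyr::summarise(n_cell = sum(.data$n), .groups = "drop")
  full <- tidyr::crossing(cells, category = scheme$labels) |>
    dplyr::left_join(counts, by = c("year", "sex", "age_band", "category")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      observed = .data$n / .data$n_cell
    ) |>
    dplyr::select("year", "sex", "age_band", "category", "observed", "n_cell")
  full$category <- factor(full$category, levels = scheme$labels)
  dplyr::arrange(full, .data$year, .data$sex, .data$age_band, .data$category) |>
    dplyr::mutate(category = as.character(.data$category))
}

#' Derive a population table from survey records
#'
#' Record counts per (year, sex, single age), usable as aggregation
#' weights so that predicted group prevalence is compared on the same age
#' composition as the observed sample.
#'
#' @param records survey records.
#' @return tibble `year`, `sex`, `age`, `count`.
#' @export
population_from_records <- function(records) {
  records |>
    dplyr::count(.data$year, .data$sex, .data$age, name = "count") |>
    dplyr::arrange(.data$year, .data$sex, .data$age)
}

#' Validate a forecast against held-out survey years
#'
#' Joins predicted and observed category prevalence over
#' (year, sex, age group, category) cells and reports the pooled mean
#' absolute error and RMSE, with per-cell residuals retained. All cells
#' are weighted equally.
#'
#' @param forecast a `bmi_forecast` from [project_prevalence()] covering
#'   the held-out years (sex-by-age-group rows are used).
#' @param heldout_records filtered survey records from the validation years.
#' @param scheme a [bmi_category_scheme()].
#' @return a `bmi_validation` list: `mae`, `mae_pct`, `rmse`, `n_cells`,
#'   `cells` (joined table with `predicted`, `observed`, `residual`).
#' @export
validate_forecast <- function(forecast, heldout_records,
                              scheme = bmi_category_scheme()) {
  obs <- observed_category_prevalence(heldout_records, scheme)
  pred <- as.data.frame(forecast)
  pred <- pred[pred$age_band != "all" & !is.na(pred$sex), , drop = FALSE]
  pred_long <- tidyr::pivot_longer(
    pred[, c("year", "sex", "age_band", scheme$labels)],
    dplyr::all_of(scheme$labels),
    names_to = "category", values_to = "predicted"
  )
  joined <- dplyr::inner_join(
    pred_long, obs, by = c("year", "sex", "age_band", "category")
  )
  if (!nrow(joined)) {
    abort_bmitraj("no overlapping (year, sex, age group) cells to validate",
                  "bmitraj_validation_error")
  }
  joined$residual <- joined$predicted - joined$observed
  structure(
    list(
      mae = mae(joined$predicted, joined$observed),
      mae_pct = 100 * mae(joined$predicted, joined$observed),
      rmse = rmse(joined$predicted, joined$observed),
      n_cells = nrow(joined),
      cells = tibble::as_tibble(joined)
    ),
    class = "bmi_validation"
  )
}

#' @export
print.bmi_validation <- function(x, ...) {
  cat(sprintf(
    "<bmi_validation> %d cells | MAE %.4f (%.2f%%) | RMSE %.4f\n",
    x$n_cells, x$mae, x$mae_pct, x$rmse
  ))
  invisible(x)
}
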