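`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
abort_bmitraj <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "bmitraj_error"), ...)
}

#' Year centring used throughout the package
#'
#' Calendar years are centred so that `year_c = 0` corresponds to 2003,
#' keeping trend coefficients on a comparable scale across models.
#'
#' @param year calendar year(s).
#' @return centred year(s), `year - 2003`.
#' @export
centre_year <- function(year) year - 2003

#' Derive a per-stage seed from a global seed
#'
#' Deterministic arithmetic derivation so that stage reruns reproduce a
#' full-pipeline run. Result always fits a 32-bit integer.
#'
#' @param seed global integer seed.
#' @param stage stage index or small integer offset.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stage) * 9973) %% 2147483647)
}

sex_label <- function(sex) {
  ifelse(sex == 1, "male", ifelse(sex == 0, "female", as.character(sex)))
}

## numeric check helper
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort_bmitraj(
      sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
      "bmitraj_argument_error"
    )
  }
  invisible(x)
}
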