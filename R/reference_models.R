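#' Reference trend coefficient sets for adult BMI in England
#'
#' Published estimates of the optimal linear-polynomial and
#' exponential-asymptote models of the position (`mu`) and shape (`sigma`)
#' of the adult log-BMI distribution in England (Health Survey for England
#' era, year centred at 2003, sex coded 1 = male / 0 = female). These sets
#' serve two roles in this package: as realistic generating truth for the
#' synthetic-data module, and as fitted models for illustrative projections
#' when no microdata are at hand.
#'
#' The non-linear family has year structure `a - b * exp(-c * year_c)`;
#' note that the published sigma model has negative `b` and `c`, i.e. its
#' exponential year term grows with time.
#'
#' @param outcome `"mu"` or `"sigma"`.
#' @param family `"linear"` or `"nonlinear"`.
#' @return A tibble with columns `term`, `estimate`, `se`.
#' @examples
#' reference_coefficients("mu", "linear")
#' @export
reference_coefficients <- function(outcome = c("mu", "sigma"),
                                   family = c("linear", "nonlinear")) {
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  tab <- switch(
    paste(family, outcome, sep = "."),
    linear.mu = tibble::tribble(
      ~term,        ~estimate,     ~se,
      "intercept",  2.972979986,   0.004964579,
      "sex",        0.014412279,   0.001611178,
      "age",        0.011426627,   0.00019795,
      "year",       0.002521202,   1.18e-04,
      "age2",      -9.53e-05,      1.78e-06,
      "year2",     -1.21e-04,      1.90e-05
    ),
    linear.sigma = tibble::tribble(
      ~term,        ~estimate,     ~se,
      "intercept", -3.806540736,   2.310486902,
      "sex",       -0.023975995,   0.008183982,
      "age",       -3.82e-04,      5.33e-04,
      "year",       0.002788139,   2.76e-04,
      "age2",      -2.76e-06,      4.48e-06,
      "year2",     -4.12e-05,      4.15e-05,
      "sex:age",   -9.37e-04,      3.38e-04,
      "sex:age2",   1.00e-05,      3.05e-06,
      "age:year",  -3.50e-05,      4.62e-06,
      "age:year2",  1.42e-06,      7.09e-07,
      "mu",         2.452629849,   1.428785876,
      "mu2",       -0.373191887,   0.221068263
    ),
    nonlinear.mu = tibble::tribble(
      ~term,        ~estimate,     ~se,
      "a",          3.005399647,   0.008456307,
      "b",          0.024797114,   0.005680661,
      "c",          0.090789991,   0.015255284,
      "sex",       -0.002427327,   0.009665538,
      "age",        0.011050057,   2.75e-04,
      "age2",      -9.18e-05,      2.46e-06,
      "sex:age",    7.87e-04,      3.95e-04,
      "sex:age2",  -7.45e-06,      3.56e-06
    ),
    nonlinear.sigma = tibble::tribble(
      ~term,        ~estimate,     ~se,
      "a",          0.176626723,   0.130804435,
      "b",         -0.018412549,   0.019345569,
      "c",         -0.048293744,   0.044582701,
      "sex",       -0.023323632,   0.009007944,
      "age",        5.21e-05,      5.78e-04,
      "age2",      -5.67e-06,      4.88e-06,
      "sex:age",   -9.73e-04,      3.70e-04,
      "sex:age2",   1.04e-05,      3.34e-06,
      "mu",         0.004283798,   0.046904444
    )
  )
  tab
}

#' Reference fitted-model objects
#'
#' Wraps [reference_coefficients()] into `bmi_fit` objects usable with
#' [predict()][predict.bmi_fit], [project_prevalence()] and
#' [project_uncertainty()]. Only standard errors were published, so the
#' coefficient covariance is approximated as diagonal (`diag(se^2)`);
#' uncertainty intervals computed from these objects ignore coefficient
#' correlation and are therefore approximate.
#'
#' @inheritParams reference_coefficients
#' @return A `bmi_fit` object.
#' @export
reference_model <- function(outcome = c("mu", "sigma"),
                            family = c("linear", "nonlinear")) {
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  tab <- reference_coefficients(outcome, family)
  cand <- candidate_model(outcome, family, tab$term)
  est <- setNames(tab$estimate, tab$term)
  se <- setNames(tab$se, tab$term)
  n_obs <- 399L
  k <- nrow(tab)
  new_bmi_fit(
    candidate = cand,
    coefficients = est,
    se = se,
    vcov = diag(se^2, nrow = k, ncol = k, names = FALSE) |>
      `dimnames<-`(list(tab$term, tab$term)),
    n_obs = n_obs,
    df_resid = n_obs - k,
    stats = list(note = "published estimates; fit statistics not recomputed"),
    converged = TRUE
  )
}
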