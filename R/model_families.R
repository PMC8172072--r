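## Candidate model grammar and fitting for the two trend families.
##
## Both families model a cohort-level outcome (mu_hat or sigma_hat) on
## sex, age and centred calendar year. The linear family is polynomial in
## year; the non-linear family replaces the year polynomial by the
## exponential-asymptote structure a - b * exp(-c * year_c).

LINEAR_TERMS <- c(
  "intercept", "sex", "age", "age2", "year", "year2",
  "sex:age", "sex:age2", "age:year", "age:year2", "sex:year", "mu", "mu2"
)
NONLINEAR_PARAMS <- c("a", "b", "c")
NONLINEAR_EXTRAS <- c("sex", "age", "age2", "sex:age", "sex:age2", "mu", "mu2")

## hierarchy: term -> terms it requires (within the optional/mandatory set)
TERM_REQUIRES <- list(
  "age2"      = "age",
  "year2"     = "year",
  "sex:age"   = c("sex", "age"),
  "sex:age2"  = c("sex:age", "age2"),
  "age:year"  = c("age", "year"),
  "age:year2" = c("age:year", "year2"),
  "sex:year"  = c("sex", "year"),
  "mu2"       = "mu"
)

#' Declare a candidate trend model
#'
#' A candidate is a term set for one outcome (`mu` or `sigma`) in one trend
#' family. Linear candidates must contain `intercept`, `sex`, `age`, `year`;
#' non-linear candidates must contain the exponential parameters `a`, `b`,
#' `c` plus `sex` and `age`. Term hierarchy is enforced: a quadratic term
#' requires its linear term, an interaction requires its components, and
#' `mu` / `mu2` terms are only allowed when the outcome is `sigma` (the
#' shape model takes the position as a covariate).
#'
#' @param outcome `"mu"` or `"sigma"`.
#' @param family `"linear"` or `"nonlinear"`.
#' @param terms character vector of term names.
#' @return A `bmi_candidate` object.
#' @examples
#' candidate_model("mu", "linear",
#'                 c("intercept", "sex", "age", "year", "age2", "year2"))
#' @export
candidate_model <- function(outcome, family, terms) {
  outcome <- match.arg(outcome, c("mu", "sigma"))
  family <- match.arg(family, c("linear", "nonlinear"))
  pool <- if (family == "linear") LINEAR_TERMS else
    c(NONLINEAR_PARAMS, NONLINEAR_EXTRAS)
  bad <- setdiff(terms, pool)
  if (length(bad)) {
    abort_bmitraj(
      sprintf("unknown term(s) for %s family: %s", family,
              paste(bad, collapse = ", ")),
      "bmitraj_schema_error"
    )
  }
  mandatory <- if (family == "linear") c("intercept", "sex", "age", "year") else
    c(NONLINEAR_PARAMS, "sex", "age")
  miss <- setdiff(mandatory, terms)
  if (length(miss)) {
    abort_bmitraj(
      sprintf("candidate lacks mandatory term(s): %s", paste(miss, collapse = ", ")),
      "bmitraj_schema_error"
    )
  }
  if (outcome == "mu" && any(c("mu", "mu2") %in% terms)) {
    abort_bmitraj("mu/mu2 terms are only permitted for sigma candidates",
                  "bmitraj_schema_error")
  }
  for (t in intersect(terms, names(TERM_REQUIRES))) {
    req <- TERM_REQUIRES[[t]]
    req <- setdiff(req, c("year"))  # in the nonlinear family year is (a,b,c)
    if (family == "linear") req <- TERM_REQUIRES[[t]]
    if (!all(req %in% terms)) {
      abort_bmitraj(
        sprintf("term `%s` requires %s", t, paste(req, collapse = ", ")),
        "bmitraj_schema_error"
      )
    }
  }
  terms <- pool[pool %in% terms]  # canonical order
  structure(
    list(
      outcome = outcome, family = family, terms = terms,
      id = paste0(outcome, "|", family, "|", paste(terms, collapse = "+"))
    ),
    class = "bmi_candidate"
  )
}

#' @export
print.bmi_candidate <- function(x, ...) {
  cat("<bmi_candidate> ", x$id, "\n", sep = "")
  invisible(x)
}

#' Number of free parameters of a candidate
#' @param candidate a `bmi_candidate`.
#' @return integer parameter count.
#' @export
n_params <- function(candidate) length(candidate$terms)

#' Enumerate hierarchy-respecting candidate models
#'
#' Builds the full candidate list for one outcome and family: every term
#' subset that contains the mandatory core (intercept, sex, age and the
#' family's year structure) and respects term hierarchy. The optional pool
#' for the linear family covers quadratics in age and year, their
#' sex/age-by-year interactions, and (for sigma) the position covariate;
#' the non-linear family carries its year structure inside (a, b, c), so
#' year-polynomial terms do not appear and its list is strictly smaller.
#'
#' @inheritParams candidate_model
#' @param optional character vector restricting the optional term pool;
#'   `NULL` (default) uses the full pool, `character(0)` yields only the
#'   mandatory candidate.
#' @return list of `bmi_candidate`, deterministic and duplicate-free.
#' @examples
#' length(enumerate_candidates("mu", "linear"))     # 50
#' length(enumerate_candidates("mu", "nonlinear"))  # 5
#' @export
enumerate_candidates <- function(outcome, family, optional = NULL) {
  outcome <- match.arg(outcome, c("mu", "sigma"))
  family <- match.arg(family, c("linear", "nonlinear"))
  if (family == "linear") {
    mandatory <- c("intercept", "sex", "age", "year")
    pool <- c("age2", "year2", "sex:age", "sex:age2",
              "age:year", "age:year2", "sex:year")
  } else {
    mandatory <- c("a", "b", "c", "sex", "age")
    pool <- c("age2", "sex:age", "sex:age2")
  }
  if (outcome == "sigma") pool <- c(pool, "mu", "mu2")
  if (!is.null(optional)) pool <- pool[pool %in% optional]
  m <- length(pool)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- pool[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    ok <- TRUE
    for (t in intersect(sel, names(TERM_REQUIRES))) {
      req <- TERM_REQUIRES[[t]]
      if (family == "nonlinear") req <- setdiff(req, "year")
      if (!all(req %in% c(mandatory, sel))) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- candidate_model(outcome, family,
                                                       c(mandatory, sel))
  }
  ## canonical order: by parameter count then id
  ord <- order(vapply(out, n_params, 1L), vapply(out, function(x) x$id, ""))
  out[ord]
}

## ---- covariate construction -------------------------------------------

## Accepts cohort observations (mean_age, mu_hat, ...) or plain covariate
## tables (sex, age, year or year_c, mu).
model_frame <- function(data) {
  df <- as.data.frame(data)
  if (!("age" %in% names(df)) && "mean_age" %in% names(df)) df$age <- df$mean_age
  if (!("year_c" %in% names(df))) {
    if ("year" %in% names(df)) df$year_c <- centre_year(df$year) else
      abort_bmitraj("need a `year` or `year_c` column", "bmitraj_schema_error")
  }
  if (!("mu" %in% names(df)) && "mu_hat" %in% names(df)) df$mu <- df$mu_hat
  df
}

term_column <- function(term, df) {
  switch(term,
    "intercept" = , "a" = rep(1, nrow(df)),
    "sex" = df$sex,
    "age" = df$age,
    "age2" = df$age^2,
    "year" = df$year_c,
    "year2" = df$year_c^2,
    "sex:age" = df$sex * df$age,
    "sex:age2" = df$sex * df$age^2,
    "age:year" = df$age * df$year_c,
    "age:year2" = df$age * df$year_c^2,
    "sex:year" = df$sex * df$year_c,
    "mu" = df$mu,
    "mu2" = df$mu^2,
    abort_bmitraj(sprintf("no column rule for term `%s`", term),
                  "bmitraj_schema_error")
  )
}

check_covariates <- function(candidate, df) {
  need <- c("sex", "age", "year_c")
  if (any(c("mu", "mu2") %in% candidate$terms)) need <- c(need, "mu")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_bmitraj(
      sprintf("candidate `%s` needs missing covariate(s): %s",
              candidate$id, paste(miss, collapse = ", ")),
      "bmitraj_schema_error"
    )
  }
}

#' Build the design matrix and response for a candidate
#'
#' For linear candidates the matrix holds one column per term in canonical
#' order (year always centred at 2003). For non-linear candidates the
#' matrix holds the terms other than the exponential triple (a, b, c), and
#' the centred year enters the fit through the `year_c` attribute.
#'
#' @param candidate a `bmi_candidate`.
#' @param observations cohort observations (or any table with `sex`, `age`
#'   or `mean_age`, `year` or `year_c`, and `mu`/`mu_hat` where required).
#' @return list with elements `X` (matrix), `y` (response vector or `NULL`
#'   when the outcome column is absent) and `year_c`.
#' @export
design_matrix <- function(candidate, observations) {
  df <- model_frame(observations)
  check_covariates(candidate, df)
  terms <- if (candidate$family == "linear") candidate$terms else
    setdiff(candidate$terms, NONLINEAR_PARAMS)
  X <- vapply(terms, term_column, numeric(nrow(df)), df = df)
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(df), dimnames = list(NULL, terms))
  ycol <- if (candidate$outcome == "mu") "mu_hat" else "sigma_hat"
  y <- if (ycol %in% names(df)) df[[ycol]] else NULL
  list(X = X, y = y, year_c = df$year_c)
}

## ---- fitted model container -------------------------------------------

new_bmi_fit <- function(candidate, coefficients, se, vcov, n_obs, df_resid,
                        stats, converged = TRUE) {
  structure(
    list(
      candidate = candidate, coefficients = coefficients, se = se,
      vcov = vcov, t_values = coefficients / se,
      p_values = 2 * pt(abs(coefficients / se), df_resid, lower.tail = FALSE),
      n_obs = n_obs, df_resid = df_resid, stats = stats, converged = converged
    ),
    class = "bmi_fit"
  )
}

#' @export
print.bmi_fit <- function(x, ...) {
  cat("<bmi_fit> ", x$candidate$id, "\n", sep = "")
  tab <- data.frame(
    estimate = x$coefficients, se = x$se,
    t = x$t_values, p = signif(x$p_values, 3)
  )
  print(tab, digits = 6)
  if (!is.null(x$stats$r_squared) && !is.na(x$stats$r_squared)) {
    cat(sprintf("R-squared %.5f  ", x$stats$r_squared))
  }
  cat(sprintf("AIC %.2f  residual df %d\n",
              x$stats$aic %||% NA_real_, x$df_resid))
  invisible(x)
}

linear_stats <- function(y, resid, k, n, family) {
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df_resid <- n - k
  sigma2 <- rss / df_resid
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  kk <- k + 1  # + residual variance
  st <- list(
    r_squared = NA_real_, adj_r_squared = NA_real_,
    residual_se = sqrt(sigma2),
    f_statistic = NA_real_, f_p_value = NA_real_,
    df_model = k, df_resid = df_resid,
    loglik = loglik, aic = 2 * kk - 2 * loglik,
    bic = kk * log(n) - 2 * loglik, deviance = rss
  )
  if (family == "linear") {
    st$r_squared <- 1 - rss / tss
    st$adj_r_squared <- 1 - (1 - st$r_squared) * (n - 1) / df_resid
    st$f_statistic <- ((tss - rss) / (k - 1)) / sigma2
    st$f_p_value <- pf(st$f_statistic, k - 1, df_resid, lower.tail = FALSE)
  }
  st
}

## ---- linear family -----------------------------------------------------

## OLS core for fit_linear(): QR solve followed by iterative refinement on
## the column-equilibrated normal equations. Polynomial designs (age^2 up
## to ~9e3 next to unit intercepts) are ill-conditioned enough that the
## raw QR solution carries ~1e-7 coefficient error; two refinement steps
## recover the least-squares solution to ~1e-12.
ols_core <- function(X, y, w = NULL) {
  fit <- if (is.null(w)) lm.fit(X, y) else stats::lm.wfit(X, y, w)
  if (fit$rank < ncol(X)) {
    abort_bmitraj("design matrix is rank deficient (singular design)",
                  "bmitraj_singular_error")
  }
  piv <- fit$qr$pivot
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  beta <- fit$coefficients[colnames(X)]
  if (is.null(w)) {
    refined <- tryCatch({
      s <- sqrt(colSums(X^2))
      Xs <- sweep(X, 2, s, "/")
      XtX <- crossprod(Xs)
      bs <- beta * s
      for (i in 1:2) bs <- bs + solve(XtX, crossprod(Xs, y - Xs %*% bs))
      drop(bs / s)
    }, error = function(e) NULL)
    if (!is.null(refined)) beta <- setNames(refined, colnames(X))
  }
  list(beta = beta, resid = drop(y - X %*% beta), xtx_inv = xtx_inv)
}

#' Fit a linear-family candidate by ordinary least squares
#'
#' OLS on the candidate's design matrix; standard errors from
#' `sigma^2 (X'X)^-1`, goodness-of-fit statistics (R-squared, adjusted
#' R-squared, residual standard error, F, log-likelihood, AIC, BIC,
#' deviance, residual df) computed under the Gaussian likelihood.
#'
#' @param candidate a linear-family `bmi_candidate`.
#' @param observations cohort observations carrying the outcome column.
#' @param weights optional non-negative case weights (cohort regressions
#'   are unweighted by default).
#' @return a `bmi_fit`.
#' @export
fit_linear <- function(candidate, observations, weights = NULL) {
  stopifnot(inherits(candidate, "bmi_candidate"))
  if (candidate$family != "linear") {
    abort_bmitraj("fit_linear() requires a linear-family candidate",
                  "bmitraj_argument_error")
  }
  dm <- design_matrix(candidate, observations)
  if (is.null(dm$y)) {
    abort_bmitraj("observations lack the outcome column", "bmitraj_schema_error")
  }
  n <- length(dm$y); k <- ncol(dm$X)
  if (n <= k) {
    abort_bmitraj("need more observations than parameters",
                  "bmitraj_insufficient_data")
  }
  core <- ols_core(dm$X, dm$y, weights)
  st <- linear_stats(dm$y, core$resid, k, n, "linear")
  vcov <- st$residual_se^2 * core$xtx_inv
  dimnames(vcov) <- list(colnames(dm$X), colnames(dm$X))
  new_bmi_fit(candidate, core$beta, sqrt(diag(vcov)), vcov, n, n - k, st)
}

## ---- non-linear family -------------------------------------------------

## Profiled residual sum of squares: for fixed c the model
##   y = a - b exp(-c yc) + X beta
## is linear in (a, b, beta). Returns +Inf when the profiled design is
## singular (e.g. c ~ 0 makes exp(-c yc) collinear with the intercept).
profile_rss <- function(cc, y, yc, X) {
  Z <- cbind(1, -exp(-cc * yc), X)
  fit <- tryCatch(lm.fit(Z, y), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(Z)) return(Inf)
  sum(fit$residuals^2)
}

profile_coefs <- function(cc, y, yc, X) {
  Z <- cbind(1, -exp(-cc * yc), X)
  lm.fit(Z, y)$coefficients
}

nl_jacobian <- function(theta, yc, X, extras) {
  a <- theta[["a"]]; b <- theta[["b"]]; cc <- theta[["c"]]
  e <- exp(-cc * yc)
  J <- cbind(a = rep(1, length(yc)), b = -e, c = b * yc * e)
  if (length(extras)) J <- cbind(J, X)
  J
}

nl_predict_theta <- function(theta, yc, X, extras) {
  out <- theta[["a"]] - theta[["b"]] * exp(-theta[["c"]] * yc)
  if (length(extras)) out <- out + drop(X %*% theta[extras])
  out
}

## Profiled search over c followed by Gauss-Newton polish with step halving.
nl_fit_core <- function(y, yc, X, extras,
                        c_intervals = list(c(-0.45, -1e-3), c(1e-3, 0.3),
                                           c(0.3, 1.5)),
                        tol = 1e-12, max_iter = 100L) {
  best <- NULL
  for (iv in c_intervals) {
    opt <- tryCatch(
      optimize(profile_rss, interval = iv, y = y, yc = yc, X = X, tol = 1e-9),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$objective) &&
        (is.null(best) || opt$objective < best$objective)) best <- opt
  }
  if (is.null(best)) {
    abort_bmitraj("non-linear fit failed: profiled search found no finite RSS",
                  "bmitraj_convergence_error")
  }
  cc <- best$minimum
  ab <- profile_coefs(cc, y, yc, X)
  theta <- c(a = unname(ab[1]), b = unname(ab[2]), c = cc)
  if (length(extras)) theta <- c(theta, setNames(ab[-(1:2)], extras))
  rss <- sum((y - nl_predict_theta(theta, yc, X, extras))^2)
  ## Gauss-Newton polish (Levenberg fallback when the normal system is
  ## ill-conditioned), step-halving line search
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - nl_predict_theta(theta, yc, X, extras)
    J <- nl_jacobian(theta, yc, X, extras)
    JtJ <- crossprod(J)
    step <- tryCatch(
      solve(JtJ, crossprod(J, r)),
      error = function(e) tryCatch(
        solve(JtJ + diag(1e-6 * pmax(diag(JtJ), 1e-8)), crossprod(J, r)),
        error = function(e2) NULL
      )
    )
    # singular even under damping (e.g. b ~ 0 makes the rate column vanish):
    # accept the current parameters as the optimum
    if (is.null(step)) { converged <- TRUE; break }
    lambda <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- theta + lambda * drop(step)
      new_rss <- sum((y - nl_predict_theta(cand, yc, X, extras))^2)
      if (is.finite(new_rss) && new_rss <= rss) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) { converged <- TRUE; break }
    rel <- (rss - new_rss) / max(rss, .Machine$double.eps)
    theta <- cand; rss <- new_rss
    if (rel < tol) { converged <- TRUE; break }
  }
  list(theta = theta, rss = rss, converged = converged)
}

#' Fit a non-linear (exponential-asymptote) candidate by least squares
#'
#' Fits `Y = a - b * exp(-c * year_c) + linear terms` by least squares.
#' The fit profiles the linear parameters out and searches the exponential
#' rate `c` over bracketing intervals (covering negative rates, since the
#' shape model can have a growing exponential term), then polishes all
#' parameters jointly by damped Gauss-Newton iteration. Standard errors
#' come from the Jacobian-based covariance at the optimum. For `c > 0` the
#' year contribution approaches the asymptote `a` as `year_c` grows; an
#' estimated `c <= 0` is flagged with a non-flattening warning (condition
#' class `bmitraj_nonflattening`), not an error.
#'
#' @param candidate a nonlinear-family `bmi_candidate`.
#' @param observations cohort observations carrying the outcome column.
#' @param c_intervals list of intervals over which the profiled rate is
#'   searched.
#' @param quiet suppress the non-flattening warning (used inside MCCV loops).
#' @return a `bmi_fit`; its statistics cover residual standard error,
#'   log-likelihood, AIC, BIC, deviance and residual df (R-squared and F
#'   are not defined for this family and reported as `NA`).
#' @export
fit_nonlinear <- function(candidate, observations,
                          c_intervals = list(c(-0.45, -1e-3), c(1e-3, 0.3),
                                             c(0.3, 1.5)),
                          quiet = FALSE) {
  stopifnot(inherits(candidate, "bmi_candidate"))
  if (candidate$family != "nonlinear") {
    abort_bmitraj("fit_nonlinear() requires a nonlinear-family candidate",
                  "bmitraj_argument_error")
  }
  dm <- design_matrix(candidate, observations)
  if (is.null(dm$y)) {
    abort_bmitraj("observations lack the outcome column", "bmitraj_schema_error")
  }
  extras <- setdiff(candidate$terms, NONLINEAR_PARAMS)
  n <- length(dm$y); k <- length(candidate$terms)
  if (n <= k) {
    abort_bmitraj("need more observations than parameters",
                  "bmitraj_insufficient_data")
  }
  core <- nl_fit_core(dm$y, dm$year_c, dm$X, extras, c_intervals = c_intervals)
  if (!core$converged) {
    abort_bmitraj("non-linear fit did not converge", "bmitraj_convergence_error",
                  best_rss = core$rss)
  }
  theta <- core$theta
  if (theta[["c"]] <= 0 && !quiet) {
    rlang::warn(
      sprintf("estimated rate c = %.4g <= 0: exponential year term does not flatten",
              theta[["c"]]),
      class = "bmitraj_nonflattening"
    )
  }
  df_resid <- n - k
  sigma2 <- core$rss / df_resid
  J <- nl_jacobian(theta, dm$year_c, dm$X, extras)
  vcov <- tryCatch(
    sigma2 * solve(crossprod(J)),
    error = function(e) {
      # J'J singular at the optimum (b ~ 0 leaves the rate unidentified):
      # pseudo-inverse keeps the identified directions finite
      sigma2 * MASS::ginv(crossprod(J))
    }
  )
  dimnames(vcov) <- list(names(theta), names(theta))
  st <- linear_stats(dm$y, dm$y - nl_predict_theta(theta, dm$year_c, dm$X, extras),
                     k, n, "nonlinear")
  new_bmi_fit(candidate, theta, sqrt(diag(vcov)), vcov, n, df_resid, st)
}

#' Fit a candidate with the fitter matching its family
#' @inheritParams fit_linear
#' @param ... passed to the family fitter.
#' @return a `bmi_fit`.
#' @export
fit_model <- function(candidate, observations, ...) {
  if (candidate$family == "linear") fit_linear(candidate, observations, ...)
  else fit_nonlinear(candidate, observations, ...)
}

#' Predict from a fitted trend model
#'
#' Deterministic evaluation of the fitted equation at new covariates.
#' `newdata` needs `sex`, `age`, and `year` or `year_c`; sigma-model
#' candidates with position terms additionally need a `mu` column.
#'
#' @param object a `bmi_fit`.
#' @param newdata data frame of covariates.
#' @param ... unused.
#' @return numeric vector of predicted outcome values.
#' @export
predict.bmi_fit <- function(object, newdata, ...) {
  dm <- design_matrix(object$candidate, newdata)
  if (object$candidate$family == "linear") {
    drop(dm$X %*% object$coefficients[colnames(dm$X)])
  } else {
    extras <- setdiff(object$candidate$terms, NONLINEAR_PARAMS)
    nl_predict_theta(object$coefficients, dm$year_c, dm$X, extras)
  }
}

#' Goodness-of-fit statistics of a fitted model
#'
#' Linear-family fits report R-squared, adjusted R-squared, residual
#' standard error, F statistic and p-value, parameter count, residual df,
#' log-likelihood, AIC, BIC and deviance. Non-linear fits report the same
#' set with R-squared and F left `NA` (not defined for this family).
#'
#' @param fitted a `bmi_fit`.
#' @return named list of statistics.
#' @export
fit_stats <- function(fitted) {
  stopifnot(inherits(fitted, "bmi_fit"))
  fitted$stats
}

#' @export
coef.bmi_fit <- function(object, ...) object$coefficients

#' @export
vcov.bmi_fit <- function(object, ...) object$vcov
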