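test_that("candidate grammar enforces hierarchy and outcome rules", {
  expect_error(candidate_model("mu", "linear", c("intercept", "sex", "age")),
               class = "bmitraj_schema_error")  # year mandatory
  expect_error(
    candidate_model("mu", "linear",
                    c("intercept", "sex", "age", "year", "year2", "age:year2")),
    class = "bmitraj_schema_error"              # age:year2 needs age:year
  )
  expect_error(
    candidate_model("mu", "linear",
                    c("intercept", "sex", "age", "year", "mu")),
    class = "bmitraj_schema_error"              # mu terms only for sigma
  )
  expect_error(candidate_model("mu", "nonlinear",
                               c("a", "b", "c", "sex", "age", "year2")),
               class = "bmitraj_schema_error")  # no year polynomial terms
  # canonical ordering regardless of input order
  c1 <- candidate_model("mu", "linear",
                        c("year", "age", "intercept", "sex", "age2"))
  expect_equal(c1$terms, c("intercept", "sex", "age", "age2", "year"))
})

test_that("candidate enumeration is deterministic, hierarchical and sized as expected", {
  lm_mu <- enumerate_candidates("mu", "linear")
  nl_mu <- enumerate_candidates("mu", "nonlinear")
  lm_sg <- enumerate_candidates("sigma", "linear")
  nl_sg <- enumerate_candidates("sigma", "nonlinear")
  expect_length(lm_mu, 50)
  expect_length(nl_mu, 5)
  expect_length(lm_sg, 150)
  expect_length(nl_sg, 15)
  expect_gt(length(lm_mu), length(nl_mu))
  expect_gt(length(lm_sg), length(nl_sg))
  ids <- vapply(lm_sg, function(x) x$id, "")
  expect_no_dup(ids)
  expect_identical(ids, vapply(enumerate_candidates("sigma", "linear"),
                               function(x) x$id, ""))
  # published optimal term sets are reachable
  expect_true(candidate_model("mu", "linear",
                              reference_coefficients("mu", "linear")$term)$id %in%
                vapply(lm_mu, function(x) x$id, ""))
  expect_true(candidate_model("sigma", "nonlinear",
                              reference_coefficients("sigma", "nonlinear")$term)$id %in%
                vapply(nl_sg, function(x) x$id, ""))
  # mandatory-only grammar collapses to a single candidate
  expect_length(enumerate_candidates("mu", "linear", optional = character(0)), 1)
  expect_length(enumerate_candidates("sigma", "nonlinear",
                                     optional = character(0)), 1)
})

test_that("design matrix uses canonical columns and centred year", {
  cand <- candidate_model("mu", "linear", c("intercept", "sex", "age", "year"))
  d <- data.frame(sex = c(0, 1, 1), age = c(20, 30, 40), year = 2035,
                  mu_hat = c(3, 3, 3))
  dm <- design_matrix(cand, d)
  expect_equal(dim(dm$X), c(3L, 4L))
  expect_equal(unname(dm$X[, "intercept"]), rep(1, 3))
  expect_equal(unname(dm$X[, "year"]), rep(32, 3))  # year = 0 in 2003

  sg <- candidate_model("sigma", "linear",
                        c("intercept", "sex", "age", "year", "mu", "mu2"))
  d$mu <- c(3.1, 3.2, 3.3)
  dm2 <- design_matrix(sg, d)
  expect_equal(unname(dm2$X[, "mu2"]), d$mu^2)
  expect_error(design_matrix(sg, d[, c("sex", "age", "year")]),
               class = "bmitraj_schema_error")
})

test_that("OLS fit is exact on noiseless data and matches lm()", {
  d <- data.frame(sex = rep(0:1, each = 10), age = rep(20:29, 2),
                  year = 2003, mu_hat = NA)
  d$mu_hat <- 1 + 2 * d$sex + 0.01 * d$age
  cand <- candidate_model("mu", "linear", c("intercept", "sex", "age", "year"))
  # year column is constant 0 here -> drop it to keep full rank
  cand2 <- candidate_model("mu", "linear", c("intercept", "sex", "age", "year"))
  d$year <- rep(c(2001, 2005), 10)
  fit <- fit_linear(cand2, d)
  expect_equal(unname(coef(fit)[c("intercept", "sex", "age")]),
               c(1, 2, 0.01), tolerance = 1e-10)
  expect_equal(fit_stats(fit)$r_squared, 1, tolerance = 1e-12)

  obs <- fix_small_obs()
  cand3 <- candidate_model("mu", "linear",
                           c("intercept", "sex", "age", "age2", "year", "year2"))
  fit3 <- fit_linear(cand3, obs)
  ref <- lm(mu_hat ~ sex + mean_age + I(mean_age^2) + year_c + I(year_c^2),
            data = obs)
  expect_equal(unname(coef(fit3)), unname(coef(ref)), tolerance = 1e-9)
  expect_equal(unname(fit3$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-9)
  st <- fit_stats(fit3)
  expect_equal(st$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(st$aic, AIC(ref), tolerance = 1e-8)
  expect_equal(st$bic, BIC(ref), tolerance = 1e-8)
  expect_equal(st$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("rank-deficient designs are refused", {
  d <- data.frame(sex = rep(0:1, 10), age = 30, year = 2003, mu_hat = rnorm(20))
  cand <- candidate_model("mu", "linear", c("intercept", "sex", "age", "year"))
  expect_error(fit_linear(cand, d), class = "bmitraj_singular_error")
})

test_that("noiseless non-linear data are recovered to machine-level accuracy", {
  for (outcome in c("mu", "sigma")) {
    truth <- ref_truth(outcome, "nonlinear")
    cand <- candidate_model(outcome, "nonlinear", names(truth))
    obs <- fix_noiseless_obs(outcome, "nonlinear")
    if (outcome == "sigma") obs$mu <- obs$mu_hat
    fit <- suppressWarnings(fit_nonlinear(cand, obs))
    expect_lt(max(abs(coef(fit) - truth[names(coef(fit))])), 1e-6)
  }
})

test_that("non-flattening rates warn and b = 0 reduces to the linear-terms model", {
  obs <- fix_noiseless_obs("sigma", "nonlinear")
  obs$mu <- obs$mu_hat
  cand <- candidate_model("sigma", "nonlinear",
                          names(ref_truth("sigma", "nonlinear")))
  expect_warning(fit_nonlinear(cand, obs), class = "bmitraj_nonflattening")

  # b = 0 truth: exponential contributes a constant; predictions equal an
  # intercept + linear-terms OLS fit
  grid <- expand.grid(sex = 0:1, age = seq(20, 80, 10), year = 1995:2010)
  grid$mu_hat <- 3 + 0.01 * grid$age + 0.02 * grid$sex
  cnl <- candidate_model("mu", "nonlinear", c("a", "b", "c", "sex", "age"))
  fnl <- suppressWarnings(fit_nonlinear(cnl, grid))
  lin <- lm(mu_hat ~ sex + age, data = grid)
  expect_lt(max(abs(predict(fnl, grid) - predict(lin, grid))), 1e-6)
})

test_that("non-linear least squares beats a coarse grid-search oracle", {
  withr::local_seed(71)
  obs <- fix_noiseless_obs("mu", "nonlinear")
  obs$mu_hat <- obs$mu_hat + rnorm(nrow(obs), 0, 0.01)
  cand <- candidate_model("mu", "nonlinear", names(ref_truth("mu", "nonlinear")))
  fit <- suppressWarnings(fit_nonlinear(cand, obs))
  rss_fit <- fit_stats(fit)$deviance

  # oracle: 3-level grid over c with (a, b, linear terms) profiled by OLS
  dm <- design_matrix(cand, obs)
  rss_grid <- min(vapply(
    c(0.01, 0.05, 0.09, 0.1, 0.5),
    function(cc) {
      Z <- cbind(1, -exp(-cc * dm$year_c), dm$X)
      sum(lm.fit(Z, dm$y)$residuals^2)
    },
    numeric(1)
  ))
  expect_lte(rss_fit, rss_grid + 1e-12)
})

test_that("non-linear fit agrees with an independent Levenberg-Marquardt solver", {
  skip_if_not_installed("minpack.lm")
  withr::local_seed(73)
  obs <- fix_noiseless_obs("mu", "nonlinear")
  obs$mu_hat <- obs$mu_hat + rnorm(nrow(obs), 0, 0.005)
  obs$year_c <- obs$year - 2003
  obs$age2 <- obs$age^2
  obs$sexage <- obs$sex * obs$age
  obs$sexage2 <- obs$sex * obs$age^2
  cand <- candidate_model("mu", "nonlinear", names(ref_truth("mu", "nonlinear")))
  fit <- suppressWarnings(fit_nonlinear(cand, obs))
  nls_fit <- minpack.lm::nlsLM(
    mu_hat ~ a - b * exp(-cc * year_c) + s * sex + g1 * age + g2 * age2 +
      g3 * sexage + g4 * sexage2,
    data = obs,
    start = list(a = 3, b = 0.02, cc = 0.1, s = 0, g1 = 0.01, g2 = -1e-4,
                 g3 = 0, g4 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  expect_equal(unname(coef(fit)), unname(coef(nls_fit)), tolerance = 1e-5)
  expect_equal(unname(fit$se),
               unname(summary(nls_fit)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("prediction evaluates the fitted equation exactly", {
  m <- reference_model("mu", "linear")
  # direct polynomial arithmetic at sex = 1, age = 40, year = 2003
  expected <- 2.972979986 + 0.014412279 + 0.011426627 * 40 - 9.53e-05 * 1600
  expect_equal(predict(m, data.frame(sex = 1, age = 40, year = 2003)),
               expected)
  expect_equal(round(expected, 4), 3.292)

  nl <- reference_model("mu", "nonlinear")
  # algebraic check at the covariate origin: a - b at year_c = 0
  expect_equal(predict(nl, data.frame(sex = 0, age = 0, year = 2003)),
               3.005399647 - 0.024797114, tolerance = 1e-12)

  # all-zero coefficients predict zero everywhere
  z <- m
  z$coefficients[] <- 0
  expect_equal(predict(z, data.frame(sex = 1, age = 77, year = 2020)), 0)

  # linearity in coefficients for the linear family
  m2 <- m
  m2$coefficients <- 2 * m$coefficients
  nd <- data.frame(sex = c(0, 1), age = c(25, 60), year = c(1995, 2030))
  expect_equal(predict(m2, nd), 2 * predict(m, nd))
})

test_that("fit statistics are internally consistent", {
  obs <- fix_small_obs()
  cand <- candidate_model("sigma", "linear",
                          c("intercept", "sex", "age", "year"))
  st <- fit_stats(fit_linear(cand, obs))
  k <- 4 + 1  # parameters + residual variance
  expect_equal(st$aic, 2 * k - 2 * st$loglik, tolerance = 1e-9)
  expect_equal(st$bic, k * log(nrow(obs)) - 2 * st$loglik, tolerance = 1e-9)
  expect_equal(st$df_resid, nrow(obs) - 4)

  # a 7-parameter model on 400 rows leaves 393 residual df
  withr::local_seed(79)
  d <- data.frame(sex = rbinom(400, 1, 0.5), age = runif(400, 18, 90),
                  year = sample(1991:2014, 400, TRUE))
  d$mu_hat <- rnorm(400, 3.2, 0.05)
  c7 <- candidate_model("mu", "linear",
                        c("intercept", "sex", "age", "age2", "year", "year2",
                          "sex:age"))
  expect_equal(fit_stats(fit_linear(c7, d))$df_resid, 393)

  # non-linear family mirrors the published convention: R^2/F not reported
  nlobs <- fix_noiseless_obs("mu", "nonlinear")
  cnl <- candidate_model("mu", "nonlinear", c("a", "b", "c", "sex", "age"))
  stnl <- fit_stats(suppressWarnings(fit_nonlinear(cnl, nlobs)))
  expect_true(is.na(stnl$r_squared))
  expect_true(is.na(stnl$f_statistic))
  expect_false(is.na(stnl$aic))
})
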