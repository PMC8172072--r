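test_that("category scheme validates cut-points", {
  sch <- bmi_category_scheme()
  expect_equal(sch$cut_points, c(18.5, 25, 30, 35))
  expect_length(sch$labels, 5)
  expect_error(bmi_category_scheme(c(25, 18.5, 30, 35)),
               class = "bmitraj_argument_error")
})

test_that("category prevalence is the lognormal CDF difference", {
  # median exactly at the 25 cut-point: lower two categories hold half the mass
  for (s in c(0.05, 0.17, 0.4)) {
    p <- category_prevalence(log(25), s)
    expect_equal(unname(p[1, 1] + p[1, 2]), 0.5)
  }
  # rows always sum to one
  p <- category_prevalence(runif(20, 2.9, 3.6), runif(20, 0.05, 0.4))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p >= 0))
  # vanishing sigma concentrates all mass in the median's category
  p0 <- category_prevalence(log(27), 1e-9)
  expect_equal(unname(p0[1, "Overweight"]), 1)
  expect_error(category_prevalence(3.2, 0), class = "bmitraj_domain_error")
})

test_that("at-risk is the upper-tail complement", {
  expect_equal(at_risk(c(0.05, 0.30, 0.35, 0.20, 0.10)), 0.65)
  p <- category_prevalence(3.25, 0.2)
  expect_equal(unname(at_risk(p[1, ]) + p[1, 1] + p[1, 2]), 1,
               tolerance = 1e-12)
  expect_equal(at_risk(category_prevalence(log(20), 1e-9)[1, ]), 0)
})

test_that("at-risk rises with mu; the obese tail rises with sigma", {
  mus <- seq(3.0, 3.6, 0.05)
  expect_true(all(diff(at_risk(category_prevalence(mus, 0.17))) > 0))
  sigmas <- seq(0.05, 0.4, 0.05)
  vo <- category_prevalence(log(25) + 0.01, sigmas)[, "Very obese"]
  expect_true(all(diff(vo) > 0))
})

test_that("two-step prediction plugs predicted position into the shape model", {
  mu_m <- reference_model("mu", "linear")
  sig_const <- reference_model("sigma", "linear")
  sig_const$coefficients[] <- 0
  sig_const$coefficients["intercept"] <- 0.17
  nd <- data.frame(sex = c(0, 1), age = c(30, 60), year = c(2000, 2030))
  ms <- predict_mu_sigma(mu_m, sig_const, nd)
  expect_equal(ms$sigma, c(0.17, 0.17))
  expect_equal(ms$mu, predict(mu_m, nd))

  # doubling the mu-term coefficient doubles that term's contribution
  sig1 <- sig_const
  sig1$coefficients["mu"] <- 0.1
  sig2 <- sig_const
  sig2$coefficients["mu"] <- 0.2
  s1 <- predict_mu_sigma(mu_m, sig1, nd)$sigma
  s2 <- predict_mu_sigma(mu_m, sig2, nd)$sigma
  expect_equal(s2 - 0.17, 2 * (s1 - 0.17))

  # non-positive shape predictions are floored with a warning
  neg <- sig_const
  neg$coefficients["intercept"] <- -1
  expect_warning(out <- predict_mu_sigma(mu_m, neg, nd),
                 class = "bmitraj_sigma_floor")
  expect_true(all(out$sigma == 0.01))
})

test_that("aggregation is the count-weighted mean and preserves normalisation", {
  labs <- bmi_category_scheme()$labels
  cells <- tibble::tibble(
    year = 2020L, sex = 0L, age = c(30L, 40L),
    Underweight = c(0.1, 0.05), `Healthy weight` = c(0.4, 0.25),
    Overweight = c(0.3, 0.4), Obese = c(0.15, 0.2), `Very obese` = c(0.05, 0.1)
  )
  pop <- tibble::tibble(year = 2020L, sex = 0L, age = c(30L, 40L),
                        count = c(100, 300))
  agg <- aggregate_prevalence(cells, pop)
  sexrow <- agg[agg$age_band == "all" & agg$sex_label == "female", ]
  expect_equal(sexrow$Underweight, (0.1 * 100 + 0.05 * 300) / 400)
  expect_equal(unname(rowSums(as.data.frame(agg)[, labs])),
               rep(1, nrow(agg)), tolerance = 1e-9)

  pop_eq <- dplyr::mutate(pop, count = 50)
  agg_eq <- aggregate_prevalence(cells, pop_eq)
  expect_equal(agg_eq[agg_eq$sex_label == "female" & agg_eq$age_band == "all", ]$Obese,
               mean(cells$Obese))

  expect_error(aggregate_prevalence(cells, pop[1, ]),
               class = "bmitraj_coverage_error")
})

test_that("projection cells multiply out the model pair deterministically", {
  mu_m <- reference_model("mu", "linear")
  sig_m <- reference_model("sigma", "linear")
  pop <- generate_population_weights(2010:2012, age_range = c(30, 40), seed = 4)
  fc1 <- project_prevalence(mu_m, sig_m, years = 2010:2012, ages = 30:40,
                            population = pop)
  fc2 <- project_prevalence(mu_m, sig_m, years = 2010:2012, ages = 30:40,
                            population = pop)
  expect_identical(as.data.frame(fc1), as.data.frame(fc2))
  labs <- bmi_category_scheme()$labels
  expect_true(all(abs(rowSums(as.data.frame(fc1)[, labs]) - 1) < 1e-9))

  # constant-in-year models forecast identically for every year
  mu_c <- mu_m
  mu_c$coefficients[c("year", "year2")] <- 0
  sig_c <- sig_m
  sig_c$coefficients[c("year", "year2", "age:year", "age:year2")] <- 0
  fcc <- project_prevalence(mu_c, sig_c, years = 2010:2012, ages = 30:40,
                            population = dplyr::mutate(pop, count = 10))
  by_year <- split(as.data.frame(fcc)[, labs], as.data.frame(fcc)$year)
  for (k in seq_along(by_year)[-1]) {
    expect_equal(by_year[[k]], by_year[[1]], ignore_attr = TRUE)
  }

  # a single-age population makes the aggregate equal that age's cell
  pop1 <- pop[pop$age == 35, ]
  fc3 <- project_prevalence(mu_m, sig_m, years = 2010, ages = 35,
                            population = pop1)
  cells <- attr(fc3, "cells")
  f <- as.data.frame(fc3)
  row <- f[f$sex_label == "female" & f$age_band != "all", labs]
  expect_equal(unname(unlist(row)),
               unname(unlist(cells[cells$sex == 0, labs])))
  pop40 <- dplyr::mutate(pop1[pop1$year == 2010, ], year = 2040L)
  expect_warning(project_prevalence(mu_m, sig_m, years = 2040, ages = 35,
                                    population = pop40),
                 "horizon")
})

test_that("uncertainty intervals behave under degenerate and dilated covariance", {
  # fitted models carry a genuine full covariance (the published reference
  # sets only have a diagonal one, which misrepresents draw dispersion)
  obs <- fix_small_obs()
  mu_m <- fit_linear(candidate_model("mu", "linear",
                                     reference_coefficients("mu", "linear")$term), obs)
  sig_m <- fit_linear(candidate_model("sigma", "linear",
                                      reference_coefficients("sigma", "linear")$term), obs)
  pop <- generate_population_weights(c(2010, 2020), age_range = c(30, 45), seed = 6)
  years <- c(2010, 2020)

  # zero covariance: intervals collapse onto the plug-in projection
  mu_0 <- mu_m; mu_0$vcov[] <- 0
  sig_0 <- sig_m; sig_0$vcov[] <- 0
  u0 <- project_uncertainty(mu_0, sig_0, years, 30:45, pop,
                            ucfg = uncertainty_config(n_draws = 50, seed = 2))
  expect_equal(u0$lower, u0$upper, tolerance = 1e-12)
  expect_equal(u0$prevalence, u0$plugin, tolerance = 1e-12)

  u1 <- project_uncertainty(mu_m, sig_m, years, 30:45, pop,
                            ucfg = uncertainty_config(n_draws = 200, seed = 2))
  # intervals bracket the plug-in projection in nearly every cell
  ok <- mean(u1$lower <= u1$plugin & u1$plugin <= u1$upper)
  expect_gte(ok, 0.95)

  # covariance x4 (all SEs doubled) widens every non-degenerate interval
  mu_w <- mu_m; mu_w$vcov <- 4 * mu_m$vcov
  sig_w <- sig_m; sig_w$vcov <- 4 * sig_m$vcov
  u4 <- project_uncertainty(mu_w, sig_w, years, 30:45, pop,
                            ucfg = uncertainty_config(n_draws = 200, seed = 2))
  expect_true(all(u4$upper - u4$lower > u1$upper - u1$lower - 1e-12))
  expect_gt(mean((u4$upper - u4$lower) / (u1$upper - u1$lower)), 1.5)
})
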