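# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

ref_truth <- function(outcome, family) {
  rc <- reference_coefficients(outcome, family)
  setNames(rc$estimate, rc$term)
}

# Default-scale synthetic study (24 years x 8000/yr, reference truth),
# seed 1: the package-wide canonical seed.
fix_default_obs <- function() {
  memo("default_obs", function() {
    cfg <- generator_config(seed = 1)
    build_cohort_dataset(assign_cohorts(filter_records(generate_survey(cfg))$records))
  })
}

# Small cohort fixture for unit tests (fast).
fix_small_obs <- function() {
  memo("small_obs", function() {
    cfg <- generator_config(years = 1998:2008, n_per_year = 2000, seed = 101)
    build_cohort_dataset(assign_cohorts(filter_records(generate_survey(cfg))$records),
                         min_cell_n = 30)
  })
}

# Noiseless grid generated from a reference model's own surface.
fix_noiseless_obs <- function(outcome, family) {
  grid <- expand.grid(sex = 0:1, age = seq(20, 90, 5), year = 1991:2014)
  mu_mod <- reference_model("mu", family)
  grid$mu_hat <- predict(mu_mod, grid)
  if (outcome == "sigma") {
    grid$sigma_hat <- predict(reference_model("sigma", family),
                              transform(grid, mu = mu_hat))
  }
  grid
}

# Independent normal-equations OLS oracle, with iterative refinement so the
# oracle's own rounding error (polynomial designs are ill-conditioned) does
# not dominate the comparison.
ols_oracle <- function(X, y) {
  s <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, s, "/")
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, y))
  for (i in 1:3) beta <- beta + solve(XtX, crossprod(Xs, y - Xs %*% beta))
  drop(beta / s)
}

expect_no_dup <- function(x) expect_equal(anyDuplicated(x), 0L)
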