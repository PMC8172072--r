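## End-to-end orchestration: simulate -> prepare -> select -> project ->
## validate, with every intermediate artifact written to disk and a run
## manifest recording config, seed and per-stage row counts.

#' Pipeline configuration
#'
#' One global seed deterministically derives per-stage seeds (via
#' [derive_seed()]), so rerunning a stage from saved artifacts reproduces
#' the full-pipeline result.
#'
#' @param outdir output directory (created if absent).
#' @param seed global integer seed.
#' @param generator a [generator_config()] (used by the simulate stage);
#'   `NULL` when reading an existing survey CSV.
#' @param survey_csv path to an existing survey CSV (`year,age,sex,bmi`);
#'   ignored when simulating.
#' @param population_csv path to a population CSV (`year,sex,age,count`);
#'   `NULL` generates synthetic weights.
#' @param fit_years survey years used for fitting/selection.
#' @param validation_years held-out survey years.
#' @param horizon last projection year.
#' @param families trend families to carry through selection/projection.
#' @param cv a [cv_config()]; its seed is overridden by the derived seed.
#' @param ucfg an [uncertainty_config()] or `NULL` to skip intervals.
#' @param scheme a [bmi_category_scheme()].
#' @param min_cell_n minimum records per cohort cell.
#' @param optional_terms optional-term restriction passed to
#'   [enumerate_candidates()] (`NULL` = full grammar).
#' @param stages character subset of
#'   `c("simulate", "prepare", "select", "project", "validate")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            generator = NULL,
                            survey_csv = NULL,
                            population_csv = NULL,
                            fit_years = 1991:2014,
                            validation_years = 2015:2017,
                            horizon = 2035,
                            families = c("linear", "nonlinear"),
                            cv = cv_config(),
                            ucfg = NULL,
                            scheme = bmi_category_scheme(),
                            min_cell_n = 50,
                            optional_terms = NULL,
                            stages = c("simulate", "prepare", "select",
                                       "project", "validate")) {
  stages <- match.arg(stages, several.ok = TRUE)
  families <- match.arg(families, c("linear", "nonlinear"), several.ok = TRUE)
  if (!("simulate" %in% stages) && is.null(survey_csv)) {
    abort_bmitraj("need `survey_csv` when the simulate stage is disabled",
                  "bmitraj_config_error")
  }
  if (!is.null(survey_csv) && !("simulate" %in% stages) && !file.exists(survey_csv)) {
    abort_bmitraj(sprintf("survey CSV not found: %s", survey_csv),
                  "bmitraj_config_error")
  }
  if (!is.null(population_csv) && !file.exists(population_csv)) {
    abort_bmitraj(sprintf("population CSV not found: %s", population_csv),
                  "bmitraj_config_error")
  }
  if (horizon < max(fit_years)) {
    abort_bmitraj("horizon must be >= last fitted year", "bmitraj_config_error")
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), generator = generator,
         survey_csv = survey_csv, population_csv = population_csv,
         fit_years = as.integer(fit_years),
         validation_years = as.integer(validation_years),
         horizon = as.integer(horizon), families = families, cv = cv,
         ucfg = ucfg, scheme = scheme, min_cell_n = min_cell_n,
         optional_terms = optional_terms, stages = stages),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `generator`, `cv` and `uncertainty` are nested maps passed to
#' [generator_config()], [cv_config()] and [uncertainty_config()]. `seed`
#' is mandatory.
#'
#' @param path YAML file path.
#' @param outdir output directory (overrides any `outdir` key).
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort_bmitraj("YAML config must set `seed`",
                                     "bmitraj_config_error")
  gen <- NULL
  if (!is.null(y$generator)) {
    g <- y$generator
    gen <- generator_config(
      years = g$years %||% 1991:2014,
      n_per_year = g$n_per_year %||% 8000,
      age_range = unlist(g$age_range %||% c(18, 95)),
      sex_ratio = g$sex_ratio %||% 0.5,
      mu_truth = if (!is.null(g$mu_truth)) unlist(g$mu_truth),
      sigma_truth = if (!is.null(g$sigma_truth)) unlist(g$sigma_truth),
      seed = g$seed %||% y$seed
    )
  }
  cv <- do.call(cv_config, c(y$cv %||% list()))
  ucfg <- if (!is.null(y$uncertainty)) do.call(uncertainty_config, y$uncertainty)
  pipeline_config(
    outdir = outdir %||% y$outdir %||% ".",
    seed = y$seed,
    generator = gen,
    survey_csv = y$survey_csv,
    population_csv = y$population_csv,
    fit_years = y$fit_years %||% 1991:2014,
    validation_years = y$validation_years %||% 2015:2017,
    horizon = y$horizon %||% 2035,
    families = y$families %||% c("linear", "nonlinear"),
    cv = cv, ucfg = ucfg,
    min_cell_n = y$min_cell_n %||% 50,
    optional_terms = y$optional_terms,
    stages = y$stages %||% c("simulate", "prepare", "select", "project",
                             "validate")
  )
}

## ---- fitted-model JSON -------------------------------------------------

#' Serialise fitted models to JSON and back
#'
#' Stores term names, estimates, standard errors, covariance and fit
#' statistics so that projection can be rerun from saved models.
#'
#' @param fits named list of `bmi_fit` objects.
#' @param path JSON file path.
#' @return `write_models_json` returns `path`; `read_models_json` a named
#'   list of `bmi_fit`.
#' @export
write_models_json <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    list(
      outcome = f$candidate$outcome, family = f$candidate$family,
      terms = f$candidate$terms,
      coefficients = as.list(f$coefficients), se = as.list(f$se),
      vcov = unname(apply(f$vcov, 1, as.list, simplify = FALSE)),
      n_obs = f$n_obs, df_resid = f$df_resid, stats = f$stats
    )
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(s) {
    terms <- unlist(s$terms)
    V <- do.call(rbind, lapply(s$vcov, function(r) unlist(r)))
    dimnames(V) <- list(terms, terms)
    new_bmi_fit(
      candidate = candidate_model(s$outcome, s$family, terms),
      coefficients = unlist(s$coefficients)[terms],
      se = unlist(s$se)[terms],
      vcov = V, n_obs = s$n_obs, df_resid = s$df_resid,
      stats = lapply(s$stats, function(x) if (is.null(x)) NA_real_ else x)
    )
  })
}

## ---- pipeline ----------------------------------------------------------

run_selection <- function(obs, outcome, family, cvc, optional_terms) {
  cands <- enumerate_candidates(outcome, family, optional = optional_terms)
  ranking <- withCallingHandlers(
    run_mccv(cands, obs, cvc),
    bmitraj_nonflattening = function(w) invokeRestart("muffleWarning")
  )
  best <- select_optimal(ranking)
  fit <- withCallingHandlers(
    fit_model(best, obs),
    bmitraj_nonflattening = function(w) invokeRestart("muffleWarning")
  )
  list(ranking = ranking, best = best, fit = fit)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or read) survey
#' microdata, prepare the cohort dataset, select optimal mu and sigma
#' models per family by Monte Carlo cross-validation, project prevalence
#' to the horizon, and validate against the held-out years — writing every
#' intermediate artifact (survey/cohort/ranking/forecast CSVs, fitted
#' model JSON, validation JSON) plus a `manifest.json` recording the
#' config hash, seed, package version and per-stage row counts. Rerunning
#' with the same config and seed reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly, with the in-memory results attached as
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "bmitraj",
    version = as.character(utils::packageVersion("bmitraj")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    stages = list()
  )
  res <- list()
  art <- function(name) file.path(config$outdir, name)

  ## -- simulate / load ---------------------------------------------------
  if ("simulate" %in% config$stages) {
    gen <- config$generator %||%
      generator_config(years = sort(unique(c(config$fit_years,
                                             config$validation_years))),
                       seed = derive_seed(config$seed, 1))
    survey <- generate_survey(gen)
    write_survey_csv(survey, art("survey.csv"))
    manifest$stages$simulate <- list(rows = nrow(survey),
                                     artifact = "survey.csv")
  } else {
    survey <- read_survey_csv(config$survey_csv)
  }
  res$survey <- survey

  ## -- prepare -----------------------------------------------------------
  if ("prepare" %in% config$stages) {
    filt <- filter_records(survey)
    fitrec <- filt$records[filt$records$year %in% config$fit_years, , drop = FALSE]
    obs <- build_cohort_dataset(assign_cohorts(fitrec), config$min_cell_n)
    write_cohort_csv(obs, art("cohort.csv"))
    manifest$stages$prepare <- list(
      rows = nrow(obs), removed_fraction = filt$removed_fraction,
      artifact = "cohort.csv"
    )
    res$cohort <- obs
    res$filtered <- filt$records
  }

  ## -- select ------------------------------------------------------------
  if ("select" %in% config$stages) {
    fits <- list()
    for (family in config$families) {
      for (outcome in c("mu", "sigma")) {
        cvc <- config$cv
        cvc$seed <- derive_seed(config$seed, 2 + match(family, config$families))
        sel <- run_selection(res$cohort, outcome, family, cvc,
                             config$optional_terms)
        key <- paste(outcome, family, sep = "_")
        write_ranking_csv(sel$ranking, art(paste0("ranking_", key, ".csv")))
        fits[[key]] <- sel$fit
        res$rankings[[key]] <- sel$ranking
      }
    }
    write_models_json(fits, art("models.json"))
    manifest$stages$select <- list(
      models = names(fits), artifact = "models.json",
      n_runs = config$cv$n_runs
    )
    res$fits <- fits
  }

  ## -- project -----------------------------------------------------------
  if ("project" %in% config$stages) {
    years <- seq(min(config$fit_years), config$horizon)
    population <- if (!is.null(config$population_csv)) {
      read_population_csv(config$population_csv)
    } else {
      generate_population_weights(years, seed = derive_seed(config$seed, 7))
    }
    res$population <- population
    for (family in config$families) {
      fc <- withCallingHandlers(
        project_prevalence(
          res$fits[[paste0("mu_", family)]],
          res$fits[[paste0("sigma_", family)]],
          years = years, ages = 18:95, population = population,
          scheme = config$scheme, horizon = config$horizon
        ),
        bmitraj_sigma_floor = function(w) invokeRestart("muffleWarning")
      )
      write_forecast_csv(fc, art(paste0("forecast_", family, ".csv")))
      res$forecast[[family]] <- fc
      if (!is.null(config$ucfg)) {
        uc <- config$ucfg
        uc$seed <- derive_seed(config$seed, 11)
        res$uncertainty[[family]] <- project_uncertainty(
          res$fits[[paste0("mu_", family)]],
          res$fits[[paste0("sigma_", family)]],
          years = c(min(years), config$horizon), ages = 18:95,
          population = population, scheme = config$scheme, ucfg = uc,
          horizon = config$horizon
        )
        write_forecast_csv(res$uncertainty[[family]],
                           art(paste0("forecast_", family, "_ci.csv")))
      }
    }
    manifest$stages$project <- list(
      families = config$families, years = c(min(years), config$horizon),
      artifact = paste0("forecast_", config$families, ".csv")
    )
  }

  ## -- validate ----------------------------------------------------------
  if ("validate" %in% config$stages) {
    held <- res$filtered[res$filtered$year %in% config$validation_years, ,
                         drop = FALSE]
    if (!nrow(held)) {
      abort_bmitraj("no held-out records in the validation years",
                    "bmitraj_validation_error")
    }
    vpop <- population_from_records(held)
    summary <- list()
    for (family in config$families) {
      vfc <- withCallingHandlers(
        project_prevalence(
          res$fits[[paste0("mu_", family)]],
          res$fits[[paste0("sigma_", family)]],
          years = config$validation_years,
          ages = sort(unique(held$age)), population = vpop,
          scheme = config$scheme, horizon = config$horizon,
          require_coverage = FALSE
        ),
        bmitraj_sigma_floor = function(w) invokeRestart("muffleWarning")
      )
      rep <- validate_forecast(vfc, held, config$scheme)
      res$validation[[family]] <- rep
      readr::write_csv(rep$cells, art(paste0("validation_", family, ".csv")))
      summary[[paste0("mae_", family)]] <- rep$mae
      summary[[paste0("rmse_", family)]] <- rep$rmse
    }
    jsonlite::write_json(summary, art("validation.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$stages$validate <- c(summary, list(artifact = "validation.json"))
  }

  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(structure(manifest, results = res))
}
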