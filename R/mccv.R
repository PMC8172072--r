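## Monte Carlo cross-validation: repeated random 80/20 splits, candidates
## fitted on training rows, scored by RMSE on test rows, ranked by
## frequency of being best.

#' Cross-validation configuration
#'
#' @param train_fraction fraction of rows in the training set (0.8 by
#'   convention: random 80/20 splits).
#' @param n_runs number of random splits (1000 by convention).
#' @param seed RNG seed for the split sequence.
#' @return a `cv_config` list.
#' @export
cv_config <- function(train_fraction = 0.8, n_runs = 1000, seed = 1L) {
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_bmitraj("train_fraction must be in (0, 1)", "bmitraj_argument_error")
  }
  check_number(n_runs, "n_runs", lower = 1)
  structure(
    list(train_fraction = train_fraction, n_runs = as.integer(n_runs),
         seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' Random train/test split of cohort observations
#'
#' Partitions rows without replacement: `round(train_fraction * n)` rows
#' to train, the rest to test. Uses the current RNG state; seed it (or use
#' [run_mccv()], which does) for reproducibility.
#'
#' @param observations data frame of rows to split.
#' @param train_fraction training fraction in (0, 1).
#' @return list with `train` and `test` data frames (disjoint, union = input).
#' @export
mccv_split <- function(observations, train_fraction = 0.8) {
  n <- nrow(observations)
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    abort_bmitraj("too few rows to split", "bmitraj_insufficient_data")
  }
  idx <- sample.int(n, n_train)
  list(train = observations[idx, , drop = FALSE],
       test = observations[-idx, , drop = FALSE])
}

#' Root mean squared error
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted)) {
    abort_bmitraj("predicted and observed must have equal non-zero length",
                  "bmitraj_argument_error")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(predicted - observed))`.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted)) {
    abort_bmitraj("predicted and observed must have equal non-zero length",
                  "bmitraj_argument_error")
  }
  mean(abs(predicted - observed))
}

## fast per-split scorers working on precomputed design matrices
score_linear <- function(X, y, idx) {
  Xtr <- X[idx, , drop = FALSE]
  fit <- tryCatch(lm.fit(Xtr, y[idx]), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(X)) return(Inf)
  pred <- drop(X[-idx, , drop = FALSE] %*% fit$coefficients[colnames(X)])
  sqrt(mean((pred - y[-idx])^2))
}

score_nonlinear <- function(X, y, yc, extras, idx, c_intervals) {
  Xtr <- X[idx, , drop = FALSE]
  res <- tryCatch(
    nl_fit_core(y[idx], yc[idx], Xtr, extras,
                c_intervals = c_intervals, tol = 1e-9, max_iter = 25L),
    error = function(e) NULL
  )
  if (is.null(res)) return(Inf)
  pred <- nl_predict_theta(res$theta, yc[-idx], X[-idx, , drop = FALSE], extras)
  sqrt(mean((pred - y[-idx])^2))
}

#' Run Monte Carlo cross-validation over a candidate list
#'
#' For each of `n_runs` random 80/20 splits, every candidate is fitted on
#' the training rows and scored by RMSE on the test rows; the run's winner
#' is the candidate with minimal test RMSE (a failed fit scores +Inf). The
#' ranking aggregates how often each candidate won. A run in which every
#' candidate fails is recorded as void and excluded from the win-frequency
#' denominator, with a warning. Fully reproducible under the config seed.
#'
#' @param candidates non-empty list of `bmi_candidate` (one outcome; both
#'   families may be mixed if they share an outcome).
#' @param observations cohort observations.
#' @param cv a [cv_config()].
#' @param c_intervals search intervals for non-linear rate parameters.
#' @return a `bmi_ranking`: tibble with `candidate_id`, `outcome`,
#'   `family`, `n_params`, `wins`, `win_frequency`, carrying attributes
#'   `n_runs`, `void_runs`, `winner_log` (per-run winner ids) and
#'   `candidates`.
#' @export
run_mccv <- function(candidates, observations, cv = cv_config(),
                     c_intervals = list(c(-0.45, -1e-3), c(1e-3, 0.3),
                                        c(0.3, 1.5))) {
  if (!length(candidates)) abort_bmitraj("no candidates supplied",
                                         "bmitraj_argument_error")
  outcomes <- unique(vapply(candidates, function(x) x$outcome, ""))
  if (length(outcomes) != 1) {
    abort_bmitraj("all candidates must share one outcome", "bmitraj_argument_error")
  }
  n <- nrow(observations)
  n_train <- round(cv$train_fraction * n)
  max_p <- max(vapply(candidates, n_params, 1L))
  if (n_train <= max_p || n_train >= n) {
    abort_bmitraj("too few observations for the requested split",
                  "bmitraj_insufficient_data")
  }
  ## precompute design matrices once
  prep <- lapply(candidates, function(cand) {
    dm <- design_matrix(cand, observations)
    list(cand = cand, X = dm$X, y = dm$y, yc = dm$year_c,
         extras = setdiff(cand$terms, NONLINEAR_PARAMS),
         linear = cand$family == "linear")
  })
  if (is.null(prep[[1]]$y)) {
    abort_bmitraj("observations lack the outcome column", "bmitraj_schema_error")
  }
  k <- length(candidates)
  wins <- integer(k)
  void <- 0L
  winner_log <- integer(cv$n_runs)
  withr::local_seed(cv$seed)
  for (run in seq_len(cv$n_runs)) {
    idx <- sample.int(n, n_train)
    scores <- vapply(prep, function(p) {
      if (p$linear) score_linear(p$X, p$y, idx)
      else score_nonlinear(p$X, p$y, p$yc, p$extras, idx, c_intervals)
    }, numeric(1))
    if (all(!is.finite(scores))) {
      void <- void + 1L
      winner_log[run] <- NA_integer_
      next
    }
    w <- which.min(scores)
    wins[w] <- wins[w] + 1L
    winner_log[run] <- w
  }
  if (void > 0) {
    rlang::warn(sprintf("%d run(s) void: every candidate failed to fit", void))
  }
  denom <- cv$n_runs - void
  ids <- vapply(candidates, function(x) x$id, "")
  tab <- tibble::tibble(
    candidate_id = ids,
    outcome = vapply(candidates, function(x) x$outcome, ""),
    family = vapply(candidates, function(x) x$family, ""),
    n_params = vapply(candidates, n_params, 1L),
    wins = wins,
    win_frequency = if (denom > 0) wins / denom else NA_real_
  )
  structure(
    tab,
    n_runs = cv$n_runs, void_runs = void,
    winner_log = tibble::tibble(
      run = seq_len(cv$n_runs),
      winner_id = ifelse(is.na(winner_log), NA_character_, ids[winner_log])
    ),
    candidates = candidates,
    class = c("bmi_ranking", class(tab))
  )
}

#' Select the optimal candidate from a ranking
#'
#' The candidate with the highest win frequency; ties broken first by
#' fewest parameters, then by lexicographically smaller canonical id.
#'
#' @param ranking a `bmi_ranking` from [run_mccv()].
#' @return the winning `bmi_candidate`.
#' @export
select_optimal <- function(ranking) {
  stopifnot(inherits(ranking, "bmi_ranking"))
  if (attr(ranking, "void_runs") >= attr(ranking, "n_runs")) {
    abort_bmitraj("all runs void: no candidate ever fitted",
                  "bmitraj_selection_error")
  }
  ord <- order(-ranking$win_frequency, ranking$n_params, ranking$candidate_id)
  attr(ranking, "candidates")[[ord[1]]]
}

#' @rdname survey_csv
#' @param ranking a `bmi_ranking`.
#' @export
write_ranking_csv <- function(ranking, path) {
  readr::write_csv(
    as.data.frame(ranking)[order(-ranking$win_frequency,
                                 ranking$n_params, ranking$candidate_id), ],
    path
  )
  invisible(path)
}
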