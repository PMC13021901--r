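#' Run the full correlation study
#'
#' For every combination of output (`co2_density`, `solubility`) and base
#' family (polynomial, KNN, gamma): tune the bagged model with
#' [tune_model()], refit it on all records with the selected configuration,
#' and evaluate [regression_metrics()] on all records.  This mirrors the
#' reference protocol of reporting correlation metrics over the complete
#' dataset; a held-out protocol is available through `holdout`.
#'
#' @param data A validated dataset; defaults to the packaged phenytoin set.
#' @param seed Integer master seed; every stochastic stage derives a child
#'   seed from it.
#' @param targets,families Character vectors selecting the grid to run.
#' @param holdout Optional fraction in (0, 1): rows are split off with a
#'   seeded draw before tuning and metrics are computed on the held-out rows
#'   instead of the fitting rows.
#' @param n_bats,n_iters Search budget forwarded to [tune_model()] for the
#'   polynomial family, whose space (degree, ridge strength, ensemble size)
#'   is three-dimensional; the two-dimensional KNN and gamma spaces use a
#'   lighter budget (`n_bats_2d`, `n_iters_2d`).
#' @param n_bats_2d,n_iters_2d Search budget for the KNN and gamma families.
#' @return An object of class `"solubag_study"`: a list with `metrics` (one
#'   tibble row per target/family in table order), `fits` (named list of
#'   tuned ensembles), `tuning` (named list of [tune_model()] results), and
#'   `seed`.
#' @examples
#' \donttest{
#' study <- run_study(phenytoin_sc_co2(), seed = 1, n_bats = 4, n_iters = 3)
#' tidy(study)
#' }
#' @export
run_study <- function(data = phenytoin_sc_co2(), seed = 20260313,
                      targets = c("co2_density", "solubility"),
                      families = c("polynomial", "knn", "gamma"),
                      holdout = NULL, n_bats = 14L, n_iters = 28L,
                      n_bats_2d = 8L, n_iters_2d = 12L) {
  data <- validate_solubility_data(data)
  eval_data <- data
  if (!is.null(holdout)) {
    if (holdout <= 0 || holdout >= 1) {
      abort("holdout must be in (0, 1)", class = "solubag_validation_error")
    }
    n_test <- max(2L, round(holdout * nrow(data)))
    test_idx <- withr::with_seed(
      child_seed(seed, 7),
      sample.int(nrow(data), n_test)
    )
    eval_data <- data[test_idx, , drop = FALSE]
    data <- data[-test_idx, , drop = FALSE]
  }

  rows <- list()
  fits <- list()
  tuning <- list()
  combo <- 0L
  for (target in targets) {
    for (family in families) {
      combo <- combo + 1L
      key <- paste(target, family, sep = ".")
      tuned <- tune_model(data, target, family,
        seed = child_seed(seed, 1000 * combo),
        n_bats = if (family == "polynomial") n_bats else n_bats_2d,
        n_iters = if (family == "polynomial") n_iters else n_iters_2d
      )
      ens <- fit_bagged(data, target, tuned$config,
        n_estimators = tuned$n_estimators,
        seed = child_seed(seed, 1000 * combo + 500)
      )
      m <- regression_metrics(
        eval_data[[target_column(target)]],
        predict(ens, eval_data)
      )
      rows[[key]] <- dplyr::bind_cols(
        tibble::tibble(target = target, family = family),
        m,
        tibble::tibble(cv_rmse = tuned$cv_rmse)
      )
      fits[[key]] <- ens
      tuning[[key]] <- tuned
    }
  }
  structure(
    list(
      metrics = dplyr::bind_rows(rows), fits = fits, tuning = tuning,
      seed = seed, holdout = holdout
    ),
    class = "solubag_study"
  )
}

#' @export
print.solubag_study <- function(x, ...) {
  cat("<solubag_study> seed", x$seed, "\n")
  print(as.data.frame(x$metrics), digits = 5)
  invisible(x)
}

#' @describeIn run_study Tidy method: the per-model metrics table.
#' @param x A `"solubag_study"`.
#' @param ... Unused.
#' @export
tidy.solubag_study <- function(x, ...) {
  x$metrics
}

#' Cross-validate a selected configuration
#'
#' Refits a fixed (already selected) bagged configuration on each training
#' fold and evaluates [regression_metrics()] on the held-out fold; no
#' re-tuning inside folds.  Folds come from [make_folds()].
#'
#' @param data A validated dataset.
#' @param target `"solubility"` or `"co2_density"`.
#' @param config A [regressor_config()] (the study-selected one).
#' @param n_estimators Ensemble size.
#' @param k_folds Number of folds.
#' @param seed Integer seed (folds and bagging).
#' @return A list with `summary` (tibble from [aggregate_cv()]), `per_fold`
#'   (tibble of fold metrics) and `folds`.
#' @export
run_cv <- function(data, target, config, n_estimators = 100L,
                   k_folds = 5L, seed = 1L) {
  data <- validate_solubility_data(data)
  folds <- make_folds(data, k_folds, seed = child_seed(seed, 77))
  ycol <- target_column(target)
  per_fold <- purrr::imap(folds, function(f, i) {
    ens <- fit_bagged(data[-f, , drop = FALSE], target, config,
      n_estimators = n_estimators, seed = child_seed(seed, 101)
    )
    m <- regression_metrics(data[[ycol]][f], predict(ens, data[f, , drop = FALSE]))
    dplyr::bind_cols(tibble::tibble(fold = as.integer(i)), m)
  }) |> dplyr::bind_rows()
  list(summary = aggregate_cv(per_fold), per_fold = per_fold, folds = folds)
}

#' Permutation feature importance
#'
#' The mean increase in whole-dataset RMSE when one feature column is
#' shuffled (breaking its relation to the response while preserving its
#' marginal distribution), averaged over `n_repeats` seeded shuffles and
#' normalized to shares summing to 1.
#'
#' @param ens A fitted `"solubag_ensemble"`.
#' @param data The dataset to permute (typically the fitting data).
#' @param target `"solubility"` or `"co2_density"`; defaults to the
#'   ensemble's target.
#' @param n_repeats Number of shuffles per feature.
#' @param seed Integer seed.
#' @return A tibble with columns `feature`, `rmse_increase`, `share`.
#' @export
feature_importance <- function(ens, data, target = NULL, n_repeats = 100L, seed = 1L) {
  data <- validate_solubility_data(data)
  target <- target %||% ens$target
  y <- data[[target_column(target)]]
  X <- as.matrix(data[, .feature_cols])
  base_rmse <- sqrt(mean((y - rowMeans(matrix(
    predict_members_core(ens, X),
    ncol = ens$n_estimators
  )))^2))
  increase <- withr::with_seed(child_seed(seed, 0), {
    vapply(seq_along(.feature_cols), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        pred <- rowMeans(matrix(predict_members_core(ens, Xp), ncol = ens$n_estimators))
        sqrt(mean((y - pred)^2)) - base_rmse
      }, numeric(1)))
    }, numeric(1))
  })
  increase <- pmax(increase, 0)
  total <- sum(increase)
  tibble::tibble(
    feature = .feature_cols,
    rmse_increase = increase,
    share = if (total > 0) increase / total else rep(1 / length(increase), length(increase))
  )
}

#' Single-variable effect curve
#'
#' Predictions of a fitted ensemble along a grid of one input with the other
#' input held fixed (at the training median by default).  Grid points
#' outside the training range are flagged as extrapolation rather than
#' refused.
#'
#' @param ens A fitted `"solubag_ensemble"` from [fit_bagged()].
#' @param varying `"T_K"` or `"P_bar"`.
#' @param fixed_value Value at which the other input is held; defaults to
#'   its training median.
#' @param grid Numeric vector of grid values; defaults to `n` points across
#'   the training range of the varying input.
#' @param n Grid length when `grid` is not given.
#' @return A tibble with the two input columns, `.pred`, and `extrapolated`.
#' @export
effect_curve <- function(ens, varying = c("T_K", "P_bar"), fixed_value = NULL,
                         grid = NULL, n = 33L) {
  varying <- match.arg(varying)
  other <- setdiff(.feature_cols, varying)
  rng <- ens$feature_ranges[[varying]]
  if (is.null(rng)) {
    abort("ensemble lacks training ranges; fit it with fit_bagged() on a dataset",
      class = "solubag_state_error"
    )
  }
  grid <- grid %||% seq(rng[1], rng[2], length.out = n)
  fixed_value <- fixed_value %||% unname(ens$feature_medians[other])
  X <- matrix(0, length(grid), 2, dimnames = list(NULL, .feature_cols))
  X[, varying] <- grid
  X[, other] <- fixed_value
  out <- tibble::as_tibble(as.data.frame(X))
  out$.pred <- predict(ens, X[, .feature_cols, drop = FALSE])
  out$extrapolated <- grid < rng[1] | grid > rng[2] |
    fixed_value < ens$feature_ranges[[other]][1] |
    fixed_value > ens$feature_ranges[[other]][2]
  out
}

#' Two-variable response surface
#'
#' Cartesian-grid evaluation of a fitted ensemble over temperature and
#' pressure, returned as a plot-ready long table.
#'
#' @param ens A fitted `"solubag_ensemble"` from [fit_bagged()].
#' @param t_grid,p_grid Numeric grid vectors; default to 33 points across
#'   the training ranges.
#' @return A tibble with columns `T_K`, `P_bar`, `.pred`.
#' @export
effect_surface <- function(ens, t_grid = NULL, p_grid = NULL) {
  t_grid <- t_grid %||% seq(ens$feature_ranges$T_K[1], ens$feature_ranges$T_K[2],
    length.out = 33
  )
  p_grid <- p_grid %||% seq(ens$feature_ranges$P_bar[1], ens$feature_ranges$P_bar[2],
    length.out = 33
  )
  grid <- tidyr::expand_grid(T_K = t_grid, P_bar = p_grid)
  grid$.pred <- predict(ens, grid)
  grid
}
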