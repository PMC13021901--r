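#' Define one hyperparameter search dimension
#'
#' @param name Parameter name.
#' @param kind `"integer"` (rounded to the nearest whole number on
#'   evaluation), `"continuous"`, or `"log"` (searched on the log10 scale).
#' @param lower,upper Box bounds on the natural scale, `lower < upper`.
#' @return A one-row tibble.
#' @export
hyper_dim <- function(name, kind = c("integer", "continuous", "log"), lower, upper) {
  kind <- match.arg(kind)
  if (!(lower < upper)) {
    abort("lower must be strictly less than upper", class = "solubag_validation_error")
  }
  if (kind == "log" && lower <= 0) {
    abort("log dimensions require positive bounds", class = "solubag_validation_error")
  }
  tibble::tibble(name = name, kind = kind, lower = lower, upper = upper)
}

#' Assemble a hyperparameter search space
#'
#' @param ... One or more [hyper_dim()] rows.
#' @return A tibble of class `"hyper_space"`.
#' @examples
#' hyper_space(
#'   hyper_dim("degree", "integer", 1, 6),
#'   hyper_dim("regularization", "log", 1e-6, 1)
#' )
#' @export
hyper_space <- function(...) {
  space <- dplyr::bind_rows(...)
  if (nrow(space) == 0) {
    abort("empty search space", class = "solubag_validation_error")
  }
  class(space) <- c("hyper_space", class(space))
  space
}

# Bounds on the internal (transformed) scale the bats fly in.
space_bounds <- function(space) {
  lo <- ifelse(space$kind == "log", log10(space$lower), space$lower)
  hi <- ifelse(space$kind == "log", log10(space$upper), space$upper)
  list(lower = lo, upper = hi)
}

# Transformed position vector -> named list of parameter values.
decode_position <- function(position, space) {
  b <- space_bounds(space)
  position <- pmin(pmax(position, b$lower), b$upper)
  vals <- as.list(position)
  for (j in seq_len(nrow(space))) {
    v <- position[j]
    if (space$kind[j] == "log") v <- 10^v
    if (space$kind[j] == "integer") {
      v <- as.integer(min(max(round(v), space$lower[j]), space$upper[j]))
    }
    vals[[j]] <- v
  }
  names(vals) <- space$name
  vals
}

#' Bat-algorithm optimization over a box-constrained space
#'
#' Population metaheuristic in which each candidate ("bat") carries a
#' position and a velocity; every iteration each bat draws a random
#' frequency vector `F ~ Uniform[0, f_max]^d` and moves by
#' `v <- v + F * (x_best - x)` followed by `x <- x + v`, with positions
#' clipped to the box.  An elitist archive retains the best position ever
#' evaluated, so the best-fitness trace is monotone non-increasing.
#'
#' Integer dimensions are rounded on evaluation and `"log"` dimensions are
#' searched on the log10 scale.  An objective value that is not finite
#' leaves the bat at its previous position with fitness `+Inf` for that
#' iteration.
#'
#' @param objective Function taking a named list of decoded parameter values
#'   and returning a scalar to minimize.
#' @param space A [hyper_space()].
#' @param n_bats Population size (>= 2).
#' @param n_iters Number of update iterations (>= 1).
#' @param f_max Upper bound of the uniform frequency draw (> 0).
#' @param seed Integer seed; runs are fully reproducible given it.
#' @return A list with `best_position` (named list, decoded), `best_fitness`,
#'   `trace` (best fitness after initialization and each iteration; length
#'   `n_iters + 1`), and `n_evaluations`.
#' @examples
#' sphere <- function(p) p$x1^2 + p$x2^2
#' sp <- hyper_space(
#'   hyper_dim("x1", "continuous", -5, 5),
#'   hyper_dim("x2", "continuous", -5, 5)
#' )
#' ba_optimize(sphere, sp, n_bats = 10, n_iters = 25, seed = 1)$best_fitness
#' @export
ba_optimize <- function(objective, space, n_bats = 20L, n_iters = 50L,
                        f_max = 1, seed = 1L) {
  if (n_bats < 2) abort("n_bats must be >= 2", class = "solubag_validation_error")
  if (n_iters < 1) abort("n_iters must be >= 1", class = "solubag_validation_error")
  if (f_max <= 0) abort("f_max must be positive", class = "solubag_validation_error")
  b <- space_bounds(space)
  d <- nrow(space)

  eval_safe <- function(pos) {
    val <- tryCatch(objective(decode_position(pos, space)), error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }

  withr::with_seed(child_seed(seed, 0), {
    X <- matrix(runif(n_bats * d, rep(b$lower, each = n_bats), rep(b$upper, each = n_bats)),
      nrow = n_bats
    )
    V <- matrix(0, n_bats, d)
    fitness <- apply(X, 1, eval_safe)
    n_evals <- n_bats
    best_i <- which.min(fitness)
    best_pos <- X[best_i, ]
    best_fit <- fitness[best_i]
    trace <- numeric(n_iters + 1)
    trace[1] <- best_fit

    for (t in seq_len(n_iters)) {
      Fmat <- matrix(runif(n_bats * d, 0, f_max), n_bats, d)
      V <- V + Fmat * (matrix(best_pos, n_bats, d, byrow = TRUE) - X)
      X_new <- X + V
      X_new <- pmin(pmax(X_new, matrix(b$lower, n_bats, d, byrow = TRUE)),
        matrix(b$upper, n_bats, d, byrow = TRUE))
      for (i in seq_len(n_bats)) {
        val <- eval_safe(X_new[i, ])
        n_evals <- n_evals + 1
        if (is.finite(val)) {
          X[i, ] <- X_new[i, ]
          fitness[i] <- val
          if (val < best_fit) {
            best_fit <- val
            best_pos <- X_new[i, ]
          }
        } else {
          fitness[i] <- Inf  # bat keeps its previous position this iteration
        }
      }
      trace[t + 1] <- best_fit
    }
  })

  list(
    best_position = decode_position(best_pos, space),
    best_raw = best_pos,
    best_fitness = best_fit,
    trace = trace,
    n_evaluations = n_evals
  )
}

#' Cross-validation folds stratified by temperature level
#'
#' Rows are grouped by temperature value, shuffled within each group from a
#' seeded generator, and dealt round-robin into `k` folds, so every fold
#' spans the temperature levels and no corner of a factorial design is held
#' out wholesale.  A fold left with fewer than 2 rows is merged into the
#' previous fold.
#'
#' @param data A validated dataset.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the within-group shuffles.
#' @return A list of integer vectors of test-row indices.
#' @export
make_folds <- function(data, k = 5L, seed = 1L) {
  data <- validate_solubility_data(data)
  n <- nrow(data)
  if (k < 2 || k > n) {
    abort("k must be in [2, n]", class = "solubag_validation_error")
  }
  fold_id <- integer(n)
  withr::with_seed(child_seed(seed, 0), {
    counter <- 0L
    for (lev in unique(data$T_K)) {
      rows <- which(data$T_K == lev)
      rows <- rows[sample.int(length(rows))]
      for (r in rows) {
        fold_id[r] <- (counter %% k) + 1L
        counter <- counter + 1L
      }
    }
  })
  folds <- split(seq_len(n), fold_id)
  names(folds) <- NULL
  # merge undersized folds into their predecessor
  i <- 2L
  while (i <= length(folds)) {
    if (length(folds[[i]]) < 2) {
      folds[[i - 1L]] <- c(folds[[i - 1L]], folds[[i]])
      folds[[i]] <- NULL
    } else {
      i <- i + 1L
    }
  }
  if (length(folds[[1]]) < 2 && length(folds) > 1) {
    folds[[2]] <- c(folds[[1]], folds[[2]])
    folds[[1]] <- NULL
  }
  folds
}

# Pooled cross-validated RMSE of a bagged configuration under fixed folds.
# Averaged over `n_repeats` independent bagging realizations so that a
# candidate cannot win on one lucky resampling draw.
cv_rmse_core <- function(data, target, config, n_estimators, folds, seed,
                         n_repeats = 2L) {
  ycol <- target_column(target)
  rmses <- vapply(seq_len(n_repeats), function(r) {
    sq_err <- numeric(0)
    for (f in folds) {
      train <- data[-f, , drop = FALSE]
      ens <- fit_bagged(train, target, config,
        n_estimators = n_estimators, seed = child_seed(seed, (r - 1) * 7001)
      )
      pred <- predict(ens, data[f, , drop = FALSE])
      sq_err <- c(sq_err, (data[[ycol]][f] - pred)^2)
    }
    sqrt(mean(sq_err))
  }, numeric(1))
  mean(rmses)
}

#' Tune a bagged model family with the bat algorithm
#'
#' Minimizes the pooled 5-fold cross-validated RMSE of the bagged model over
#' the family's hyperparameter space (polynomial: expansion degree, ridge
#' strength, ensemble size; gamma: ridge strength and ensemble size, with the
#' linear predictor of the printed GLM form; KNN: number of neighbours,
#' ensemble size).  The objective is repeated cross-validation: two seeded
#' fold partitions, each evaluated with its own bagging realization, and the
#' pooled RMSEs averaged.  Partitions and bagging seeds are fixed across all
#' candidate evaluations, so the objective is deterministic and candidates
#' are compared under identical conditions.
#'
#' @param data A validated dataset.
#' @param target `"solubility"` or `"co2_density"`.
#' @param family `"polynomial"`, `"knn"` or `"gamma"`.
#' @param seed Integer master seed (folds, bagging, and the optimizer derive
#'   child seeds from it).
#' @param n_bats,n_iters,f_max Bat-algorithm settings; the defaults give a
#'   search of about 250 candidate evaluations.
#' @param k_folds Number of cross-validation folds.
#' @param n_estimators_range Integer bounds of the ensemble-size dimension.
#' @return A list with `config` (a [regressor_config()]), `n_estimators`,
#'   `cv_rmse` (the best objective value), `trace`, and `folds`.
#' @export
tune_model <- function(data, target, family = c("polynomial", "knn", "gamma"),
                       seed = 1L, n_bats = 12L, n_iters = 20L, f_max = 1,
                       k_folds = 5L, n_estimators_range = c(10L, 200L)) {
  family <- match.arg(family)
  data <- validate_solubility_data(data)
  # Repeated cross-validation: two fold partitions, each with its own
  # bagging realization, averaged.  A single 5-fold split of 32 points is
  # too noisy an objective and lets the optimizer exploit partition luck.
  partitions <- list(
    make_folds(data, k_folds, seed = child_seed(seed, 78)),
    make_folds(data, k_folds, seed = child_seed(seed, 79))
  )
  min_train <- nrow(data) - max(lengths(partitions[[1]]))
  bag_seeds <- c(child_seed(seed, 101), child_seed(seed, 8102))

  est_dim <- hyper_dim(
    "n_estimators", "integer",
    n_estimators_range[1], n_estimators_range[2]
  )
  # The gamma GLM keeps its printed linear predictor (degree 1): letting its
  # expansion degree float makes it a polynomial model on the log scale and
  # erases the distinction between the two families.
  space <- switch(family,
    knn = hyper_space(
      hyper_dim("k_neighbors", "integer", 1, max(min_train - 1, 2)), est_dim
    ),
    polynomial = hyper_space(
      hyper_dim("degree", "integer", 1, 6),
      hyper_dim("regularization", "log", 1e-6, 1),
      est_dim
    ),
    gamma = hyper_space(
      hyper_dim("regularization", "log", 1e-6, 1),
      est_dim
    )
  )

  objective <- function(p) {
    config <- switch(family,
      knn = regressor_config("knn", k_neighbors = p$k_neighbors),
      polynomial = regressor_config("polynomial",
        degree = p$degree, regularization = p$regularization
      ),
      gamma = regressor_config("gamma",
        degree = 1L, regularization = p$regularization
      )
    )
    mean(vapply(seq_along(partitions), function(i) {
      cv_rmse_core(data, target, config, p$n_estimators,
        partitions[[i]], bag_seeds[i],
        n_repeats = 1L
      )
    }, numeric(1)))
  }

  res <- ba_optimize(objective, space,
    n_bats = n_bats, n_iters = n_iters,
    f_max = f_max, seed = child_seed(seed, 13)
  )
  best <- res$best_position
  config <- switch(family,
    knn = regressor_config("knn", k_neighbors = best$k_neighbors),
    polynomial = regressor_config("polynomial",
      degree = best$degree, regularization = best$regularization
    ),
    gamma = regressor_config("gamma",
      degree = 1L, regularization = best$regularization
    )
  )
  list(
    config = config,
    n_estimators = best$n_estimators,
    cv_rmse = res$best_fitness,
    trace = res$trace,
    folds = partitions
  )
}
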