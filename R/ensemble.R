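#' Fit a bagged ensemble of base learners
#'
#' Bootstrap aggregation: `n_estimators` with-replacement resamples ("bags")
#' of size `round(bootstrap_fraction * n)` are drawn from a seeded generator
#' (bag `b` uses child seed `seed + b`), one base learner is fitted per bag,
#' and predictions are the arithmetic mean over members.  A bag whose base
#' fit fails (singular system, diverging IRLS) is redrawn deterministically,
#' at most 5 times, before the error is propagated.
#'
#' All members share one standardization state computed from the full
#' fitting set, stored on the ensemble; with `bootstrap = FALSE` and one
#' member the ensemble is exactly the base learner fitted on the data.
#'
#' @param data A validated dataset.
#' @param target `"solubility"` or `"co2_density"`.
#' @param config A [regressor_config()].
#' @param n_estimators Number of bags (members), a positive integer.
#' @param bootstrap_fraction Bag size as a fraction of `n`, in (0, 1].
#' @param seed Integer seed; the fit is fully reproducible given it.
#' @param bootstrap If `FALSE`, every member is trained on the identity bag
#'   (the full data, no resampling); useful for degenerate-case checks.
#' @return An object of class `"solubag_ensemble"`.
#' @examples
#' ens <- fit_bagged(phenytoin_sc_co2(), "co2_density",
#'   regressor_config("polynomial", degree = 3),
#'   n_estimators = 25, seed = 1
#' )
#' head(predict(ens, phenytoin_sc_co2()))
#' @export
fit_bagged <- function(data, target, config, n_estimators = 100L,
                       bootstrap_fraction = 1, seed = 1L, bootstrap = TRUE) {
  data <- validate_solubility_data(data)
  if (nrow(data) < 3) {
    abort("at least 3 records are required", class = "solubag_validation_error")
  }
  X <- as.matrix(data[, .feature_cols])
  y <- data[[target_column(target)]]
  ens <- fit_bagged_core(X, y, config, n_estimators, bootstrap_fraction, seed, bootstrap)
  ens$target <- target
  ens$feature_ranges <- list(
    T_K = range(data$T_K), P_bar = range(data$P_bar)
  )
  ens$feature_medians <- c(T_K = median(data$T_K), P_bar = median(data$P_bar))
  ens
}

fit_bagged_core <- function(X, y, config, n_estimators = 100L,
                            bootstrap_fraction = 1, seed = 1L, bootstrap = TRUE) {
  if (n_estimators < 1 || n_estimators != round(n_estimators)) {
    abort("n_estimators must be a positive integer", class = "solubag_validation_error")
  }
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    abort("bootstrap_fraction must be in (0, 1]", class = "solubag_validation_error")
  }
  n <- nrow(X)
  m <- max(3L, as.integer(round(bootstrap_fraction * n)))
  scaler <- make_scaler(X)
  Xs <- apply_scaler(X, scaler)

  ens <- list(
    base_config = config, n_estimators = as.integer(n_estimators),
    bootstrap_fraction = bootstrap_fraction, rng_seed = as.integer(seed),
    scaler = scaler, family = config$family, n_train = n
  )

  coef_based <- config$family %in% c("polynomial", "gamma")
  if (coef_based) {
    M <- polynomial_terms(Xs, config$degree)
    pw <- penalty_weights(attr(M, "total_degree"))
    ens$term_names <- colnames(M)
    ens$term_degrees <- attr(M, "total_degree")
    gamma_start <- NULL
    if (config$family == "gamma") {
      # warm start every member's IRLS from the full-data fit
      gamma_start <- fit_gamma_core(M, y, config$regularization, pw)$coefficients
    }
    coefs <- matrix(0, ncol(M), n_estimators)
  } else {
    if (config$k_neighbors > m) {
      abort("k_neighbors exceeds the bag size", class = "solubag_validation_error")
    }
    bags <- vector("list", n_estimators)
  }

  fit_one <- function(idx) {
    if (coef_based) {
      w <- tabulate(idx, nbins = n)
      if (config$family == "polynomial") {
        solve_ridge(M, y, config$regularization, pw, wobs = w)
      } else {
        fit_gamma_core(M, y, config$regularization, pw,
          wobs = w, start = gamma_start
        )$coefficients
      }
    } else {
      idx
    }
  }

  # per-bag child seeds (seed + bag index); the caller's RNG stream is
  # preserved around the whole loop
  withr::with_preserve_seed({
    for (b in seq_len(n_estimators)) {
      fitted <- NULL
      for (retry in 0:5) {
        idx <- if (bootstrap) {
          set.seed(child_seed(seed, b + 1000003 * retry))
          sample.int(n, m, replace = TRUE)
        } else {
          seq_len(n)
        }
        fitted <- tryCatch(fit_one(idx), error = function(e) NULL)
        if (!is.null(fitted) || !bootstrap) break
      }
      if (is.null(fitted)) {
        abort(sprintf("base fit failed on bag %d after 5 redraws", b),
          class = "solubag_rank_error"
        )
      }
      if (coef_based) coefs[, b] <- fitted else bags[[b]] <- fitted
    }
  })

  if (coef_based) {
    ens$member_coefficients <- coefs
  } else {
    ens$bags <- bags
    ens$training_points <- Xs
    ens$training_targets <- y
  }
  structure(ens, class = "solubag_ensemble")
}

# Member-wise prediction matrix (rows = query points, cols = members).
predict_members_core <- function(object, X) {
  Xs <- apply_scaler(X, object$scaler)
  if (object$family %in% c("polynomial", "gamma")) {
    M <- polynomial_terms(Xs, object$base_config$degree)
    eta <- M %*% object$member_coefficients
    if (object$family == "gamma") exp(eta) else eta
  } else {
    k <- object$base_config$k_neighbors
    vapply(object$bags, function(idx) {
      knn_predict_core(
        object$training_points[idx, , drop = FALSE],
        object$training_targets[idx], Xs, min(k, length(idx))
      )
    }, numeric(nrow(Xs)))
  }
}

#' Predict from a bagged ensemble
#'
#' @param object A `"solubag_ensemble"` from [fit_bagged()].
#' @param newdata A dataset with `T_K`/`P_bar` columns, or a 2-column matrix.
#' @param members If `TRUE`, return the full member-by-query prediction
#'   matrix instead of the row-wise mean.
#' @param ... Unused.
#' @return A numeric vector (default) or a matrix with one column per member.
#' @export
predict.solubag_ensemble <- function(object, newdata, members = FALSE, ...) {
  P <- predict_members_core(object, feature_matrix(newdata))
  P <- matrix(P, ncol = object$n_estimators)
  if (members) P else rowMeans(P)
}

#' @export
print.solubag_ensemble <- function(x, ...) {
  cat(
    "<solubag_ensemble>", x$n_estimators, "x", x$family,
    "on", x$n_train, "points\n"
  )
  if (!is.null(x$target)) cat("  target:", x$target, "\n")
  invisible(x)
}

#' Tidy a bagged ensemble
#'
#' For coefficient-based families (polynomial, gamma) returns one row per
#' expanded term with the across-member mean and SD of the coefficient.  For
#' KNN returns one row per member with its bag composition.
#'
#' @param x A `"solubag_ensemble"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.solubag_ensemble <- function(x, ...) {
  if (x$family %in% c("polynomial", "gamma")) {
    tibble::tibble(
      term = x$term_names,
      total_degree = x$term_degrees,
      estimate = rowMeans(x$member_coefficients),
      std_error = apply(x$member_coefficients, 1, sd)
    )
  } else {
    tibble::tibble(
      member = seq_along(x$bags),
      bag_size = lengths(x$bags),
      n_unique = vapply(x$bags, function(i) length(unique(i)), integer(1))
    )
  }
}

#' One-row summary of a bagged ensemble
#'
#' @param x A `"solubag_ensemble"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.solubag_ensemble <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    target = x$target %||% NA_character_,
    n_estimators = x$n_estimators,
    bootstrap_fraction = x$bootstrap_fraction,
    n_train = x$n_train,
    rng_seed = x$rng_seed
  )
}
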