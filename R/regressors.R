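#' Base-learner configuration
#'
#' One configuration object covers the three weak-learner families.  Only the
#' fields relevant to `family` are consulted: `degree` and `regularization`
#' for `"polynomial"` and `"gamma"` (both fit on the expanded monomial basis
#' of [polynomial_terms()]), `k_neighbors` and `distance_metric` for `"knn"`.
#'
#' `regularization` is the ridge strength `lambda` of a smoothness-weighted
#' penalty: the squared coefficient of a term with total degree g is
#' penalized by `lambda * 4^g` (the intercept is never penalized).  With
#' `regularization = 0` and a full-rank design the fit is exactly ordinary
#' least squares.  The degree weighting exists to keep high-order terms in
#' check on bootstrap resamples that under-represent corners of the design;
#' see the package vignette.
#'
#' @param family `"polynomial"`, `"knn"` or `"gamma"`.
#' @param degree Maximum total degree of the monomial expansion, in `[1, 6]`.
#' @param k_neighbors Number of neighbours for KNN, a positive integer.
#' @param regularization Nonnegative ridge strength for polynomial/gamma.
#' @param distance_metric KNN metric; only `"euclidean"` is supported.
#' @return A list of class `"regressor_config"`.
#' @examples
#' regressor_config("polynomial", degree = 3)
#' @export
regressor_config <- function(family = c("polynomial", "knn", "gamma"),
                             degree = 2L,
                             k_neighbors = 5L,
                             regularization = 1e-8,
                             distance_metric = "euclidean") {
  family <- match.arg(family)
  if (degree < 1 || degree > 6 || degree != round(degree)) {
    abort("degree must be an integer in [1, 6]", class = "solubag_validation_error")
  }
  if (k_neighbors < 1 || k_neighbors != round(k_neighbors)) {
    abort("k_neighbors must be a positive integer", class = "solubag_validation_error")
  }
  if (!identical(distance_metric, "euclidean")) {
    abort("only the euclidean distance metric is supported",
      class = "solubag_validation_error"
    )
  }
  if (regularization < 0) {
    abort("regularization must be nonnegative", class = "solubag_validation_error")
  }
  structure(
    list(
      family = family, degree = as.integer(degree),
      k_neighbors = as.integer(k_neighbors),
      regularization = regularization, distance_metric = distance_metric
    ),
    class = "regressor_config"
  )
}

#' @export
print.regressor_config <- function(x, ...) {
  cat("<regressor_config>", x$family, "\n")
  if (x$family == "knn") {
    cat("  k_neighbors:", x$k_neighbors, " metric:", x$distance_metric, "\n")
  } else {
    cat("  degree:", x$degree, " regularization:", format(x$regularization), "\n")
  }
  invisible(x)
}

# Penalty weight per expanded term: 0 for the intercept, 4^degree otherwise.
penalty_weights <- function(total_degree) {
  ifelse(total_degree == 0, 0, 4^total_degree)
}

# Weighted penalized least squares on an expanded design.
# wobs: nonnegative observation weights (bootstrap multiplicities or IRLS).
solve_ridge <- function(M, y, lambda, pw, wobs = NULL) {
  if (is.null(wobs)) {
    A <- crossprod(M)
    b <- crossprod(M, y)
  } else {
    A <- crossprod(M, wobs * M)
    b <- crossprod(M, wobs * y)
  }
  diag(A) <- diag(A) + lambda * pw
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    abort("singular normal equations; increase regularization or reduce degree",
      class = "solubag_rank_error"
    )
  }
  drop(backsolve(ch, forwardsolve(t(ch), b)))
}

# Gamma GLM with log link via penalized IRLS.  For the log link the working
# weights are constant, so each step is a penalized least-squares solve on
# the working response z = eta + (y - mu)/mu.  Deviance-based convergence.
fit_gamma_core <- function(M, y, lambda, pw, wobs = NULL, start = NULL,
                           max_iter = 100L, tol = 1e-10) {
  if (any(y <= 0)) {
    abort("gamma regression requires strictly positive targets",
      class = "solubag_domain_error"
    )
  }
  beta <- start %||% solve_ridge(M, log(y), lambda, pw, wobs)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  w <- if (is.null(wobs)) rep(1, length(y)) else wobs
  for (iter in seq_len(max_iter)) {
    eta <- drop(M %*% beta)
    mu <- exp(eta)
    if (any(!is.finite(mu))) {
      abort("gamma IRLS diverged (non-finite mean)",
        class = "solubag_convergence_error", last_coefficients = beta
      )
    }
    z <- eta + (y - mu) / mu
    beta <- solve_ridge(M, z, lambda, pw, wobs)
    mu_new <- exp(drop(M %*% beta))
    dev <- 2 * sum(w * (-log(y / mu_new) + (y - mu_new) / mu_new))
    if (!is.finite(dev)) {
      abort("gamma IRLS diverged (non-finite deviance)",
        class = "solubag_convergence_error", last_coefficients = beta
      )
    }
    if (abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    abort(sprintf("gamma IRLS did not converge in %d iterations", max_iter),
      class = "solubag_convergence_error", last_coefficients = beta
    )
  }
  mu <- exp(drop(M %*% beta))
  n_eff <- sum(w > 0)
  pearson <- sum(w * ((y - mu) / mu)^2)
  dispersion <- pearson / max(n_eff - ncol(M), 1)
  list(
    coefficients = beta, dispersion = dispersion,
    deviance = dev, iterations = iter
  )
}

# Fit one base learner on raw feature matrix X and target y, using the given
# standardization state (computed by the caller: own data for standalone
# fits, the full fitting set for ensemble members).
fit_regressor_core <- function(X, y, config, scaler, wobs = NULL,
                               gamma_start = NULL) {
  Xs <- apply_scaler(X, scaler)
  fit <- list(
    family = config$family, config = config, scaler = scaler,
    n_train = nrow(Xs)
  )
  if (config$family == "knn") {
    if (config$k_neighbors > nrow(Xs)) {
      abort("k_neighbors exceeds the number of training points",
        class = "solubag_validation_error"
      )
    }
    fit$training_points <- Xs
    fit$training_targets <- y
  } else {
    M <- polynomial_terms(Xs, config$degree)
    pw <- penalty_weights(attr(M, "total_degree"))
    if (config$family == "polynomial") {
      fit$coefficients <- solve_ridge(M, y, config$regularization, pw, wobs)
    } else {
      g <- fit_gamma_core(M, y, config$regularization, pw, wobs, start = gamma_start)
      fit$coefficients <- g$coefficients
      fit$dispersion <- g$dispersion
      fit$deviance <- g$deviance
    }
    names(fit$coefficients) <- colnames(M)
    fit$term_degrees <- attr(M, "total_degree")
  }
  structure(fit, class = "solubag_regressor")
}

#' Fit a single base learner
#'
#' Fits one of the three weak-learner families on a dataset.  Features are
#' z-score standardized (training mean/SD) before the monomial expansion or
#' distance computation; the standardization state is stored on the fitted
#' object and re-applied at prediction time.
#'
#' @param data A validated dataset (see [validate_solubility_data()]).
#' @param target `"solubility"` or `"co2_density"`.
#' @param config A [regressor_config()].
#' @return An object of class `"solubag_regressor"`.
#' @examples
#' fit <- fit_regressor(phenytoin_sc_co2(), "co2_density",
#'   regressor_config("polynomial", degree = 2)
#' )
#' predict(fit, phenytoin_sc_co2())[1:3]
#' @export
fit_regressor <- function(data, target, config) {
  data <- validate_solubility_data(data)
  if (nrow(data) < 3) {
    abort("at least 3 records are required for any fit",
      class = "solubag_validation_error"
    )
  }
  X <- as.matrix(data[, .feature_cols])
  y <- data[[target_column(target)]]
  fit_regressor_core(X, y, config, make_scaler(X))
}

# Feature matrix from either a dataset or a bare 2-column matrix.
feature_matrix <- function(newdata) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != 2) {
      abort("feature matrix must have two columns (T, P)",
        class = "solubag_validation_error"
      )
    }
    return(newdata)
  }
  missing_cols <- setdiff(.feature_cols, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata lacks columns: ", paste(missing_cols, collapse = ", ")),
      class = "solubag_schema_error"
    )
  }
  as.matrix(newdata[, .feature_cols])
}

predict_regressor_core <- function(object, X) {
  Xs <- apply_scaler(X, object$scaler)
  if (object$family == "knn") {
    return(knn_predict_core(
      object$training_points, object$training_targets,
      Xs, object$config$k_neighbors
    ))
  }
  M <- polynomial_terms(Xs, object$config$degree)
  eta <- drop(M %*% object$coefficients)
  if (object$family == "gamma") exp(eta) else eta
}

#' Predict from a fitted base learner
#'
#' @param object A `"solubag_regressor"` from [fit_regressor()].
#' @param newdata A dataset with `T_K`/`P_bar` columns, or a 2-column matrix.
#' @param ... Unused.
#' @return A numeric vector of predictions, one per row.
#' @export
predict.solubag_regressor <- function(object, newdata, ...) {
  predict_regressor_core(object, feature_matrix(newdata))
}

#' @export
print.solubag_regressor <- function(x, ...) {
  cat("<solubag_regressor>", x$family, "on", x$n_train, "points\n")
  invisible(x)
}

#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return The Euclidean norm of `a - b`.
#' @examples
#' knn_distance(c(0, 0), c(3, 4))  # 5
#' @export
knn_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort("vectors must have equal length", class = "solubag_validation_error")
  }
  sqrt(sum((a - b)^2))
}

# K-nearest-neighbour mean prediction on standardized coordinates.
# Ties at the k-th distance are broken by training index (earlier row wins),
# which order() guarantees via its stable sort.
knn_predict_core <- function(train_points, train_targets, query_points, k) {
  n <- nrow(train_points)
  if (n == 0) {
    abort("empty training set", class = "solubag_state_error")
  }
  k <- min(k, n)
  tr_sq <- rowSums(train_points^2)
  q_sq <- rowSums(query_points^2)
  cross <- query_points %*% t(train_points)
  d2 <- pmax(outer(q_sq, tr_sq, "+") - 2 * cross, 0)
  apply(d2, 1, function(row) mean(train_targets[order(row)[seq_len(k)]]))
}

#' KNN prediction for explicit query points
#'
#' The unweighted mean of the targets of the `k` training points nearest to
#' each query under the Euclidean distance on standardized features.
#'
#' @param model A fitted KNN `"solubag_regressor"`.
#' @param newdata A dataset or 2-column feature matrix of query points.
#' @param k Number of neighbours; defaults to the model's configuration.
#' @return Numeric vector of predictions.
#' @export
knn_predict <- function(model, newdata, k = NULL) {
  if (!inherits(model, "solubag_regressor") || model$family != "knn") {
    abort("model must be a fitted KNN regressor", class = "solubag_state_error")
  }
  k <- k %||% model$config$k_neighbors
  if (k < 1 || k > model$n_train) {
    abort("k must be in [1, n_train]", class = "solubag_validation_error")
  }
  Xs <- apply_scaler(feature_matrix(newdata), model$scaler)
  knn_predict_core(model$training_points, model$training_targets, Xs, k)
}
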