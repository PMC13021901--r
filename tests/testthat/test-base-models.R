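test_that("polynomial expansion follows the graded-lex contract", {
  expect_equal(unname(polynomial_terms(matrix(c(2, 3), 1), 1)[1, ]), c(1, 2, 3))
  # oracle: enumerate (a, b) with a + b <= 2 by hand on (T = 2, P = 3)
  expect_equal(unname(polynomial_terms(matrix(c(2, 3), 1), 2)[1, ]), c(1, 2, 3, 4, 6, 9))
  for (deg in 1:6) {
    ex <- polynomial_exponents(deg)
    expect_equal(nrow(ex), choose(deg + 2, 2))
    expect_true(all(diff(ex$total_degree) >= 0)) # graded order
  }
  expect_equal(
    colnames(polynomial_terms(matrix(c(2, 3), 1), 2)),
    c("T^0.P^0", "T^1.P^0", "T^0.P^1", "T^2.P^0", "T^1.P^1", "T^0.P^2")
  )
})

test_that("unpenalized polynomial fit equals the normal-equations oracle", {
  d <- tiny_grid_data()
  withr::with_seed(42, {
    d$co2_density <- d$co2_density + rnorm(nrow(d), 0, 5)
  })
  for (deg in 1:2) {
    fit <- fit_regressor(d, "co2_density",
      regressor_config("polynomial", degree = deg, regularization = 0)
    )
    M <- polynomial_terms(std_cols(d[, c("T_K", "P_bar")]), deg)
    beta <- unname(drop(solve(t(M) %*% M, t(M) %*% d$co2_density)))
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
    expect_equal(predict(fit, d), drop(M %*% beta), tolerance = 1e-8)
  }
})

test_that("polynomial fit interpolates in-model data and obeys the ridge limit", {
  d <- tiny_grid_data()
  d$co2_density <- 3 * d$T_K + 500 # exactly linear in T
  fit <- fit_regressor(d, "co2_density",
    regressor_config("polynomial", degree = 1, regularization = 0)
  )
  expect_equal(predict(fit, d), d$co2_density, tolerance = 1e-8)
  # penalty -> Inf: slope terms vanish, prediction -> mean(y)
  heavy <- fit_regressor(d, "co2_density",
    regressor_config("polynomial", degree = 2, regularization = 1e12)
  )
  expect_equal(predict(heavy, d), rep(mean(d$co2_density), nrow(d)), tolerance = 1e-4)
})

test_that("euclidean distance matches its defining sum", {
  expect_equal(knn_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(knn_distance(c(0, 0), c(3, 4)), 5)
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- rnorm(4)
      b <- rnorm(4)
      acc <- 0
      for (k in seq_along(a)) acc <- acc + (a[k] - b[k])^2
      expect_equal(knn_distance(a, b), sqrt(acc))
      expect_equal(knn_distance(a, b), knn_distance(b, a))
    }
  })
  expect_error(knn_distance(1:2, 1:3), class = "solubag_validation_error")
})

test_that("knn prediction equals the brute-force sort oracle", {
  withr::with_seed(11, {
    for (rep in 1:100) {
      n <- sample(5:15, 1)
      d <- tibble::tibble(
        T_K = runif(n, 300, 350), P_bar = runif(n, 90, 260),
        y = runif(n, 0.5, 10), co2_density = runif(n, 200, 900)
      )
      k <- sample(seq_len(n), 1)
      fit <- fit_regressor(d, "solubility", regressor_config("knn", k_neighbors = k))
      q <- c(runif(1, 300, 350), runif(1, 90, 260))
      got <- knn_predict(fit, matrix(q, 1))
      # oracle: standardize, compute all distances, full sort, take first k
      Xs <- std_cols(d[, c("T_K", "P_bar")])
      qs <- (q - colMeans(d[, c("T_K", "P_bar")])) / apply(d[, c("T_K", "P_bar")], 2, sd)
      dd <- sqrt((Xs[, 1] - qs[1])^2 + (Xs[, 2] - qs[2])^2)
      expect_equal(got, mean(d$y[order(dd)[1:k]]))
    }
  })
})

test_that("knn limits: full neighbourhood mean, zero-distance neighbour, tie rule", {
  d <- tiny_grid_data()
  fit <- fit_regressor(d, "solubility", regressor_config("knn", k_neighbors = nrow(d)))
  expect_equal(predict(fit, matrix(c(400, 400), 1)), mean(d$y))
  one <- fit_regressor(d, "solubility", regressor_config("knn", k_neighbors = 1))
  expect_equal(predict(one, d[3, ]), d$y[3])
  # exact duplicate (T, P) rows with different targets: earlier row wins at k = 1
  dup <- d
  dup[5, c("T_K", "P_bar")] <- dup[4, c("T_K", "P_bar")]
  fit1 <- fit_regressor(dup, "solubility", regressor_config("knn", k_neighbors = 1))
  expect_equal(predict(fit1, dup[4, ]), dup$y[4])
  # permutation invariance of the training set (distinct distances)
  perm <- withr::with_seed(3, sample.int(nrow(d)))
  fit_a <- fit_regressor(d, "solubility", regressor_config("knn", k_neighbors = 3))
  fit_b <- fit_regressor(d[perm, ], "solubility", regressor_config("knn", k_neighbors = 3))
  q <- matrix(c(321.5, 170.1), 1)
  expect_equal(predict(fit_a, q), predict(fit_b, q))
})

test_that("gamma GLM matches stats::glm on an unpenalized fit", {
  d <- tiny_grid_data(n_t = 5, n_p = 6)
  withr::with_seed(5, {
    mult <- rgamma(nrow(d), shape = 50, rate = 50)
  })
  d$y <- d$y * mult
  fit <- fit_regressor(d, "solubility",
    regressor_config("gamma", degree = 1, regularization = 0)
  )
  Xs <- std_cols(d[, c("T_K", "P_bar")])
  ref <- stats::glm(d$y ~ Xs, family = stats::Gamma(link = "log"))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$dispersion, summary(ref)$dispersion, tolerance = 1e-4)
})

test_that("gamma fit recovers coefficients of a synthetic log-linear surface", {
  n <- 200
  withr::with_seed(21, {
    x1 <- runif(n, -1, 1)
    x2 <- runif(n, -1, 1)
    mu <- exp(0.5 + 0.8 * x1 - 0.3 * x2)
    y <- mu * rgamma(n, shape = 100, rate = 100) # tiny gamma noise
  })
  d <- tibble::tibble(
    T_K = 330 + 15 * x1, P_bar = 170 + 75 * x2,
    y = y, co2_density = rep(500, n)
  )
  fit <- fit_regressor(d, "solubility",
    regressor_config("gamma", degree = 1, regularization = 0)
  )
  Xs <- std_cols(d[, c("T_K", "P_bar")])
  ref <- stats::glm(y ~ Xs, family = stats::Gamma(link = "log"))
  se <- summary(ref)$coefficients[, "Std. Error"]
  # ground truth mapped onto the standardized scale the model fits on
  truth <- c(
    0.5 + 0.8 * mean(x1) - 0.3 * mean(x2),
    0.8 * sd(x1), -0.3 * sd(x2)
  )
  expect_true(all(abs(unname(fit$coefficients) - truth) < 3 * se))
})

test_that("gamma predictions are positive, exact for constant targets, and scale-equivariant", {
  d <- tiny_grid_data()
  const <- d
  const$y <- rep(2.5, nrow(d))
  # intercept-only (degree-1 fit on constant y drives slopes to ~0)
  fit <- fit_regressor(const, "solubility", regressor_config("gamma", degree = 1))
  expect_equal(predict(fit, const), rep(2.5, nrow(const)), tolerance = 1e-8)
  fit2 <- fit_regressor(d, "solubility", regressor_config("gamma", degree = 2))
  grid <- as.matrix(expand.grid(T_K = c(200, 400), P_bar = c(50, 500)))
  expect_true(all(predict(fit2, grid) > 0))
  # scaling y by c shifts only the intercept, by log(c)
  scaled <- d
  scaled$y <- d$y * 7
  fit7 <- fit_regressor(scaled, "solubility", regressor_config("gamma", degree = 2))
  expect_equal(fit7$coefficients[1] - fit2$coefficients[1], c(`T^0.P^0` = log(7)),
    tolerance = 1e-6
  )
  expect_equal(unname(fit7$coefficients[-1]), unname(fit2$coefficients[-1]),
    tolerance = 1e-6
  )
  expect_error(
    fit_regressor(
      transform(d, y = y - max(y)), "solubility",
      regressor_config("gamma")
    ),
    class = "solubag_validation_error"
  )
})

test_that("all three families are deterministic given data and config", {
  d <- tiny_grid_data()
  q <- as.matrix(expand.grid(T_K = c(315, 340), P_bar = c(120, 230)))
  for (cfg in list(
    regressor_config("polynomial", degree = 3),
    regressor_config("knn", k_neighbors = 4),
    regressor_config("gamma", degree = 2)
  )) {
    p1 <- predict(fit_regressor(d, "co2_density", cfg), q)
    p2 <- predict(fit_regressor(d, "co2_density", cfg), q)
    expect_identical(p1, p2)
  }
})
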