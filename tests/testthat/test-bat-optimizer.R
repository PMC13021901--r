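test_that("one optimizer iteration follows the velocity/position equations", {
  sp <- hyper_space(hyper_dim("x", "continuous", -10, 10))
  seed <- 314L
  res <- ba_optimize(function(p) p$x^2, sp, n_bats = 2, n_iters = 1, f_max = 1, seed = seed)
  # oracle: replay the seeded draws and apply the two update rules by hand
  oracle <- withr::with_seed(solubag:::child_seed(seed, 0), {
    x0 <- runif(2, -10, 10)
    f0 <- x0^2
    best <- x0[which.min(f0)]
    Fv <- runif(2, 0, 1)
    v1 <- 0 + Fv * (best - x0) # v <- v + F (x_best - x)
    x1 <- pmin(pmax(x0 + v1, -10), 10) # x <- x + v, clipped
    f1 <- x1^2
    list(trace = c(min(f0), min(c(f0, f1))), best = min(c(f0, f1)))
  })
  expect_equal(res$trace, oracle$trace)
  expect_equal(res$best_fitness, oracle$best)
})

test_that("the incumbent best bat is a fixed point of the update", {
  # constant objective: the first bat stays incumbent, has zero velocity,
  # and must never move
  sp <- hyper_space(hyper_dim("x", "continuous", -3, 3))
  seed <- 99L
  res <- ba_optimize(function(p) 5, sp, n_bats = 3, n_iters = 20, seed = seed)
  x_init_first <- withr::with_seed(solubag:::child_seed(seed, 0), runif(3, -3, 3))[1]
  expect_equal(res$best_position$x, x_init_first)
  expect_equal(res$best_fitness, 5)
})

test_that("runs are deterministic given the seed and traces are monotone", {
  sp <- hyper_space(
    hyper_dim("x1", "continuous", -5, 5),
    hyper_dim("x2", "continuous", -5, 5)
  )
  sphere <- function(p) p$x1^2 + p$x2^2
  r1 <- ba_optimize(sphere, sp, n_bats = 10, n_iters = 30, seed = 7)
  r2 <- ba_optimize(sphere, sp, n_bats = 10, n_iters = 30, seed = 7)
  expect_identical(r1$trace, r2$trace)
  expect_equal(length(r1$trace), 31)
  for (s in 1:5) {
    tr <- ba_optimize(sphere, sp, n_bats = 8, n_iters = 25, seed = s)$trace
    expect_true(all(diff(tr) <= 0))
  }
})

test_that("the sphere benchmark converges and improves with iterations", {
  sp <- hyper_space(
    hyper_dim("x1", "continuous", -5, 5),
    hyper_dim("x2", "continuous", -5, 5)
  )
  sphere <- function(p) p$x1^2 + p$x2^2
  expect_lt(ba_optimize(sphere, sp, n_bats = 20, n_iters = 100, seed = 1)$best_fitness, 1e-2)
  finals <- vapply(1:20, function(s) {
    c(
      ba_optimize(sphere, sp, n_bats = 10, n_iters = 5, seed = s)$best_fitness,
      ba_optimize(sphere, sp, n_bats = 10, n_iters = 100, seed = s)$best_fitness
    )
  }, numeric(2))
  expect_lt(median(finals[2, ]), median(finals[1, ]))
})

test_that("integer dimensions always decode to in-range integers", {
  sp <- hyper_space(
    hyper_dim("k", "integer", 1, 7),
    hyper_dim("lam", "log", 1e-6, 1)
  )
  seen <- new.env()
  seen$k <- integer(0)
  seen$lam <- numeric(0)
  obj <- function(p) {
    seen$k <- c(seen$k, p$k)
    seen$lam <- c(seen$lam, p$lam)
    abs(p$k - 3) + abs(log10(p$lam) + 2)
  }
  res <- ba_optimize(obj, sp, n_bats = 6, n_iters = 15, seed = 2)
  expect_true(all(seen$k == round(seen$k)))
  expect_true(all(seen$k >= 1 & seen$k <= 7))
  expect_true(all(seen$lam >= 1e-6 & seen$lam <= 1))
  expect_equal(res$best_position$k, 3L)
})

test_that("non-finite objective values do not derail the search", {
  sp <- hyper_space(hyper_dim("x", "continuous", -2, 2))
  obj <- function(p) if (p$x > 0) Inf else p$x^2
  res <- ba_optimize(obj, sp, n_bats = 6, n_iters = 20, seed = 5)
  expect_true(is.finite(res$best_fitness))
  expect_lte(res$best_position$x, 0)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("stratified folds partition the data and respect the merge rule", {
  d <- phenytoin_sc_co2()
  folds <- make_folds(d, 5, seed = 1)
  expect_equal(sort(unlist(folds)), 1:32)
  expect_true(all(lengths(folds) >= 2))
  # stratification: every fold spans several temperature levels
  for (f in folds) {
    expect_gte(length(unique(d$T_K[f])), 3)
  }
  # k close to n forces merging until every fold has >= 2 test rows
  tiny <- tiny_grid_data(n_t = 3, n_p = 3)
  folds9 <- make_folds(tiny, 9, seed = 2)
  expect_true(all(lengths(folds9) >= 2))
  expect_equal(sort(unlist(folds9)), 1:9)
})

test_that("tuning recovers the generating degree of a quadratic surface", {
  gen <- generate_dataset(generator_spec(
    n_temps = 5, n_pressures = 6, dispersion = 0.003, seed = 10
  ))
  tuned <- tune_model(gen$data, "co2_density", "polynomial",
    seed = 3, n_bats = 8, n_iters = 12
  )
  # oracle: exhaustive scan over degrees under the same repeated-CV objective
  obj_by_degree <- vapply(1:4, function(deg) {
    cfg <- regressor_config("polynomial",
      degree = deg,
      regularization = tuned$config$regularization
    )
    mean(c(
      solubag:::cv_rmse_core(
        gen$data, "co2_density", cfg, tuned$n_estimators,
        tuned$folds[[1]], solubag:::child_seed(3, 101),
        n_repeats = 1
      ),
      solubag:::cv_rmse_core(
        gen$data, "co2_density", cfg, tuned$n_estimators,
        tuned$folds[[2]], solubag:::child_seed(3, 8102),
        n_repeats = 1
      )
    ))
  }, numeric(1))
  expect_equal(tuned$config$degree, which.min(obj_by_degree))
  expect_equal(tuned$config$degree, 2L)
  # the tuned objective value is no worse than the default configuration's
  default_obj <- mean(c(
    solubag:::cv_rmse_core(
      gen$data, "co2_density", regressor_config("polynomial"), 100,
      tuned$folds[[1]], solubag:::child_seed(3, 101),
      n_repeats = 1
    ),
    solubag:::cv_rmse_core(
      gen$data, "co2_density", regressor_config("polynomial"), 100,
      tuned$folds[[2]], solubag:::child_seed(3, 8102),
      n_repeats = 1
    )
  ))
  expect_lte(tuned$cv_rmse, default_obj + 1e-12)
})
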