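#' Specification for the synthetic surface generator
#'
#' Describes a full temperature-by-pressure factorial design with two smooth
#' positive response surfaces that mimic the statistical structure of
#' supercritical-CO2 measurements: a density surface that decreases with
#' temperature and increases with pressure, and a solubility surface whose
#' logarithm increases in both inputs, observed with multiplicative
#' (gamma-like) noise.
#'
#' Surface coefficients are given in the graded-lexicographic monomial basis
#' of [polynomial_terms()] over grid-standardized (T, P); the vector length
#' must be `choose(d + 2, 2)` for some degree `d`.  `dispersion` is the
#' squared coefficient of variation of the noise, identical in meaning for
#' both noise models (gamma multiplier: shape `1/dispersion`, unit mean;
#' gaussian: sd equal to `sqrt(dispersion)` times the local mean).
#'
#' @param n_temps,n_pressures Grid sizes (>= 2 each).
#' @param t_range,p_range Inclusive (lower, upper) grid ranges in K and bar.
#' @param density_coefficients Polynomial coefficients of the density mean
#'   surface (kg m^-3 scale).
#' @param solubility_log_coefficients Coefficients of the log-mean
#'   solubility surface.
#' @param density_noise `"gaussian"` (default) or `"gamma"` noise for the
#'   density column; solubility noise is always a gamma multiplier, matching
#'   the gamma-regression assumption.
#' @param dispersion Positive squared coefficient of variation of the noise.
#' @param seed Integer seed.
#' @return A list of class `"generator_spec"`.
#' @examples
#' generate_dataset(generator_spec(seed = 1))$data
#' @export
generator_spec <- function(n_temps = 4L, n_pressures = 8L,
                           t_range = c(313, 345), p_range = c(95, 250),
                           density_coefficients = c(600, -160, 120, -20, 25, -25),
                           solubility_log_coefficients = c(1.0, 0.9, 0.8, 0.1, 0.25, -0.1),
                           density_noise = c("gaussian", "gamma"),
                           dispersion = 0.01, seed = 1L) {
  density_noise <- match.arg(density_noise)
  if (n_temps < 2 || n_pressures < 2) {
    abort("grid sizes must be at least 2", class = "solubag_validation_error")
  }
  if (dispersion <= 0) {
    abort("dispersion must be positive", class = "solubag_validation_error")
  }
  for (cf in list(density_coefficients, solubility_log_coefficients)) {
    d <- (sqrt(8 * length(cf) + 1) - 3) / 2
    if (abs(d - round(d)) > 1e-9) {
      abort("coefficient vectors must have choose(d + 2, 2) entries for integer degree d",
        class = "solubag_validation_error"
      )
    }
  }
  structure(
    list(
      n_temps = as.integer(n_temps), n_pressures = as.integer(n_pressures),
      t_range = t_range, p_range = p_range,
      density_coefficients = density_coefficients,
      solubility_log_coefficients = solubility_log_coefficients,
      density_noise = density_noise, dispersion = dispersion,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

# Degree implied by a graded-lex coefficient vector.
coef_degree <- function(cf) as.integer(round((sqrt(8 * length(cf) + 1) - 3) / 2))

# Unit-mean gamma multiplier with squared coefficient of variation `disp`.
gamma_multiplier <- function(n, disp) {
  shape <- 1 / disp
  rgamma(n, shape = shape, rate = shape)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Builds the full factorial (T, P) grid of the spec, evaluates the two mean
#' surfaces, and adds seeded noise: a gamma multiplier for solubility and
#' (by default) mean-proportional gaussian noise for density, truncated away
#' from zero so responses stay strictly positive.
#'
#' @param spec A [generator_spec()].
#' @return A list with `data` (a tibble in the canonical dataset schema) and
#'   `truth` (the same grid with the noiseless `density_mean` and
#'   `solubility_mean` surfaces).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "generator_spec")) {
    abort("spec must be a generator_spec", class = "solubag_validation_error")
  }
  t_vals <- seq(spec$t_range[1], spec$t_range[2], length.out = spec$n_temps)
  p_vals <- seq(spec$p_range[1], spec$p_range[2], length.out = spec$n_pressures)
  grid <- tidyr::expand_grid(T_K = t_vals, P_bar = p_vals)
  X <- as.matrix(grid)
  Xs <- apply_scaler(X, make_scaler(X))

  dens_mean <- drop(polynomial_terms(Xs, coef_degree(spec$density_coefficients)) %*%
    spec$density_coefficients)
  sol_mean <- exp(drop(
    polynomial_terms(Xs, coef_degree(spec$solubility_log_coefficients)) %*%
      spec$solubility_log_coefficients
  ))
  if (any(dens_mean <= 0) || any(!is.finite(sol_mean))) {
    abort("spec produces non-positive or non-finite mean surfaces",
      class = "solubag_validation_error"
    )
  }

  n <- nrow(grid)
  withr::with_seed(child_seed(spec$seed, 0), {
    sol <- sol_mean * gamma_multiplier(n, spec$dispersion)
    dens <- if (spec$density_noise == "gamma") {
      dens_mean * gamma_multiplier(n, spec$dispersion)
    } else {
      dens_mean + rnorm(n, 0, sqrt(spec$dispersion) * dens_mean)
    }
  })
  # truncate away from zero: responses are physically positive
  dens <- pmax(dens, 1e-6 * dens_mean)
  sol <- pmax(sol, 1e-6 * sol_mean)

  data <- tibble::tibble(
    T_K = grid$T_K, P_bar = grid$P_bar,
    y = sol, co2_density = dens
  )
  truth <- tibble::tibble(
    T_K = grid$T_K, P_bar = grid$P_bar,
    density_mean = dens_mean, solubility_mean = sol_mean
  )
  list(data = validate_solubility_data(data), truth = truth)
}
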