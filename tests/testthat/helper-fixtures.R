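# Shared test fixtures, built in code.

# Small smooth dataset on a T x P grid with known structure.
tiny_grid_data <- function(n_t = 4, n_p = 5,
                           f_y = function(T, P) exp(0.005 * T + 0.004 * P),
                           f_dens = function(T, P) 1000 - 2 * T + 1.5 * P) {
  g <- expand.grid(
    T_K = seq(310, 350, length.out = n_t),
    P_bar = seq(100, 250, length.out = n_p)
  )
  tibble::tibble(
    T_K = g$T_K, P_bar = g$P_bar,
    y = f_y(g$T_K, g$P_bar),
    co2_density = f_dens(g$T_K, g$P_bar)
  )
}

# Manual standardization matching the package's scaler.
std_cols <- function(X) {
  sweep(sweep(as.matrix(X), 2, colMeans(X)), 2, apply(X, 2, sd), "/")
}

# The expensive tuned study on the packaged dataset, computed once per test
# run and reused by every block that needs it.
.study_cache <- new.env(parent = emptyenv())
study_fixture <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- run_study(phenytoin_sc_co2(), seed = 20260313)
  }
  .study_cache$study
}
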