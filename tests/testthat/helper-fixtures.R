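# Shared fixtures. Unit tests run on a coarse 44-band grid and small
# boosters to stay fast; the acceptance tests build their own full-size
# fixtures. Heavy objects are memoized per test run.

small_grid <- function() wavelength_grid(470, 900, 10)

fast_cfg <- function(seed = 1) {
  gbt_config(n_estimators = 30, min_child_weight = 1, max_depth = 4,
             learning_rate = 0.3, seed = seed)
}

# a small noisy training table on the coarse grid
small_table <- function(seed = 1, counts = 6,
                        params = spectral_model_params()) {
  generate_calibration_set(ph_points = seq(5, 9, 1),
                           po2_points = c(0, 50, 100, 195),
                           counts = counts, params = params,
                           grid = small_grid(), seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small trained cascade shared across unit tests
small_cascade <- function() {
  memo("small_cascade", {
    tab <- small_table(seed = 11)
    train_cascade(tab, cfg_ph = fast_cfg(1), cfg_o2 = fast_cfg(2))
  })
}
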