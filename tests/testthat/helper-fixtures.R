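# Shared fixtures. Everything is generated in code; the heavier synthetic
# datasets are memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tag_vial <- function(...) {
  vial_from_geometry(3.75e-6, 14e-3, 50e-6 / 915, oil_density = 915, ...)
}

# gentle single-fatty-acid constants: fastest timescale ~ 0.03 / s, so an
# explicit fixed-step integrator can serve as an independent oracle
toy_constants <- function() {
  m <- matrix(0, 18, 3, dimnames = list(
    c("ki", "kp1", "kp2", "kd", "kbimol", "kpro1", "kpro2", "ke1", "ke2",
      "ke3", "ke4", "kald", "kket", "kloh1", "kloh2", "kt1", "kt2", "kt3"),
    fatty_acids()))
  m[, "18:1"] <- c(1e-10, 1e-2, 1e-4, 1e-6, 1e-8, 0, 0, 1e-5, 1e-5,
                   1e-5, 1e-5, 2e-5, 1e-5, 1e-5, 1e-5, 1e-2, 1e-2, 1e-2)
  rate_constant_set(m, enforce_fe_ratio = FALSE)
}

toy_config <- function(t_days = seq(0, 0.25, length.out = 6), ...) {
  sim_config(composition = c("18:1" = 1), temperature_C = 40,
             t_days = t_days, vial = tag_vial(), LOOH0 = 5, ...)
}

# small noise-free trilinolein dataset (single temperature)
tl_dataset_clean <- function() {
  memo("tl_clean", {
    des <- preset_design("trilinolein", rsd = 0, n_samples = 12)
    des$temps_C <- 25
    des$horizons_days <- 120
    generate_dataset(des, seed = 1)
  })
}

# the standard noisy four-temperature trilinolein dataset
tl_dataset_noisy <- function() {
  memo("tl_noisy", generate_dataset(preset_design("trilinolein"), seed = 42))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
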