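# Antioxidant scavenging: decay prediction, stoichiometry, efficacy
# estimation from the induction period, and the critical-hydroperoxide
# acceleration fit.

oil_vial <- function(...) {
  vial_from_geometry(20.4e-6, 20.5e-3, 1e-6, oil_density = 920, ...)
}
oil_comp <- c("18:1" = 0.62, "18:2" = 0.19, "18:3" = 0.08, saturated = 0.11)

test_that("tocopherol is inert without its constants and otherwise only decays", {
  k0 <- default_constants(40)
  k0$shared[] <- 0
  cfg <- sim_config(oil_comp, 40, t_days = seq(0, 60, length.out = 13),
                    vial = oil_vial(), AH0 = 1, LOOH0 = 4)
  ah <- predict_ah_decay(k0, cfg)
  expect_equal(ah$AH, rep(1, 13), tolerance = 1e-8)
  # with scavenging active the curve is non-increasing and non-negative
  k <- default_constants(40)
  ah2 <- predict_ah_decay(k, cfg)
  expect_true(all(diff(ah2$AH) <= 1e-10))
  expect_true(all(ah2$AH >= 0))
  expect_lt(ah2$AH[13], ah2$AH[1])
})

test_that("every antioxidant molecule breaks two radical chains", {
  # only initiation, AH scavenging of peroxyl radicals, and the
  # antioxidant-radical trap are active: radicals in sustained excess
  m <- matrix(0, 18, 3, dimnames = dimnames(rate_constant_set()$perfa))
  m["ki", "18:1"] <- 1e-9
  k <- rate_constant_set(m, shared = c(kAH1 = 500, kt4 = 1000),
                         enforce_fe_ratio = FALSE)
  cfg <- sim_config(c("18:1" = 1), 40, t_days = seq(0, 30, length.out = 16),
                    vial = tag_vial(), AH0 = 0.05, LOOH0 = 0,
                    rtol = 1e-9, atol = 1e-12)
  traj <- simulate_oxidation(cfg, k)
  y0 <- traj$states[1, ]; y1 <- traj$states[16, ]
  dAH <- y0[["AH"]] - y1[["AH"]]
  expect_gt(dAH, 0.04)   # antioxidant nearly exhausted
  # peroxyl radicals consumed by the antioxidant cycle: one forms LOOH
  # (scavenging), one is trapped by A. into NRP
  loo_consumed <- (y1[["LOOH.18:1"]] - y0[["LOOH.18:1"]]) +
    (y1[["NRP"]] - y0[["NRP"]])
  expect_equal(loo_consumed / dAH, 2, tolerance = 0.01)
})

test_that("more antioxidant means less hydroperoxide during induction", {
  k <- default_constants(40)
  grid <- seq(0, 40, length.out = 9)
  looh <- lapply(c(0, 0.5, 1), function(ah0) {
    cfg <- sim_config(oil_comp, 40, t_days = grid, vial = oil_vial(),
                      AH0 = ah0, LOOH0 = 4)
    class_totals(simulate_oxidation(cfg, k))$LOOH
  })
  expect_true(all(looh[[2]] <= looh[[1]] + 1e-8))
  expect_true(all(looh[[3]] <= looh[[2]] + 1e-8))
})

test_that("antioxidant constants are fitted from early LOOH only, lipids frozen", {
  ktruth <- default_constants(40)
  ktruth$shared[] <- 0
  ktruth <- set_constant(ktruth, "kAH1", 500)
  cfg <- sim_config(oil_comp, 40, t_days = seq(0, 60, length.out = 13),
                    vial = oil_vial(), AH0 = 1, LOOH0 = 4)
  ct <- class_totals(simulate_oxidation(cfg, ktruth))
  sel <- ct$LOOH <= 10
  dat <- data.frame(substrate = "oil", temperature_C = 40,
                    product_class = "LOOH", fatty_acid = NA,
                    time_days = ct$time_days[sel][-1],
                    conc_mmol_per_kg = ct$LOOH[sel][-1],
                    sd = 0.02 * ct$LOOH[sel][-1], censored = FALSE)
  ds <- ox_dataset(dat, setNames(list(cfg), "40"))
  kstart <- set_constant(ktruth, "kAH1", 100)
  fa <- fit_antioxidant(ds, kstart, spec = fit_spec("kAH1"), n_starts = 2)
  expect_false(fa$unidentifiable)
  expect_lt(abs(fa$constants[["kAH1"]] / 500 - 1), 0.05)
  # freezing contract: every lipid constant bit-identical to the input
  expect_identical(fa$k$perfa, kstart$perfa)
  # the fitted model stays below the antioxidant-free prediction early on
  cfg0 <- cfg; cfg0$AH0 <- 0
  looh_no_ah <- class_totals(simulate_oxidation(cfg0, fa$k))$LOOH
  looh_fit <- class_totals(simulate_oxidation(cfg, fa$k))$LOOH
  expect_true(all(looh_fit[2:6] < looh_no_ah[2:6]))
})

test_that("antioxidant constants are reported unidentifiable without antioxidant", {
  ktruth <- default_constants(40)
  cfg <- sim_config(oil_comp, 40, t_days = seq(0, 2, length.out = 17),
                    vial = oil_vial(), AH0 = 0, LOOH0 = 4)
  ct <- class_totals(simulate_oxidation(cfg, ktruth))
  sel <- which(ct$LOOH <= 10)[-1]
  dat <- data.frame(substrate = "oil", temperature_C = 40,
                    product_class = "LOOH", fatty_acid = NA,
                    time_days = ct$time_days[sel],
                    conc_mmol_per_kg = ct$LOOH[sel],
                    sd = 0.1, censored = FALSE)
  ds <- ox_dataset(dat, setNames(list(cfg), "40"))
  expect_warning(fa <- fit_antioxidant(ds, ktruth), "unidentifiable")
  expect_true(fa$unidentifiable)
  # and an empty early window is an error
  dat2 <- dat; dat2$conc_mmol_per_kg <- dat2$conc_mmol_per_kg + 100
  ds2 <- ox_dataset(dat2, setNames(list(cfg), "40"))
  expect_error(fit_antioxidant(ds2, ktruth), "insufficient")
})

test_that("the critical concentration and acceleration factor are recoverable", {
  k20 <- default_constants(20)
  cfg <- sim_config(oil_comp, 20, t_days = seq(0, 720, length.out = 91),
                    vial = oil_vial(P_cap = 1e-11), AH0 = 1, LOOH0 = 4,
                    accel = accel_policy(enabled = TRUE, C_crit = 113, f = 3))
  ct <- class_totals(simulate_oxidation(cfg, k20))
  dat <- data.frame(substrate = "oil", temperature_C = 20,
                    product_class = "LOOH", fatty_acid = NA,
                    time_days = ct$time_days[-1],
                    conc_mmol_per_kg = ct$LOOH[-1], sd = 0,
                    censored = FALSE)
  cfg_base <- cfg; cfg_base$accel <- accel_policy()
  ds <- ox_dataset(dat, setNames(list(cfg_base), "20"))
  fc <- fit_acceleration(ds, k20, C_starts = c(80, 95), f_start = 2,
                         maxit = 40)
  expect_true(fc$identifiable)
  expect_lt(abs(fc$C_crit / 113 - 1), 0.05)
  expect_lt(abs(fc$f / 3 - 1), 0.10)
  # both starting thresholds converge to the same optimum
  expect_lt(diff(range(fc$per_start$C_crit)), 1)
})

test_that("data without acceleration yield no identifiable acceleration", {
  k20 <- default_constants(20)
  cfg <- sim_config(oil_comp, 20, t_days = seq(0, 720, length.out = 61),
                    vial = oil_vial(P_cap = 1e-11), AH0 = 1, LOOH0 = 4)
  ct <- class_totals(simulate_oxidation(cfg, k20))
  dat <- data.frame(substrate = "oil", temperature_C = 20,
                    product_class = "LOOH", fatty_acid = NA,
                    time_days = ct$time_days[-1],
                    conc_mmol_per_kg = ct$LOOH[-1], sd = 0,
                    censored = FALSE)
  ds <- ox_dataset(dat, setNames(list(cfg), "20"))
  fc <- fit_acceleration(ds, k20, maxit = 25)
  expect_false(fc$identifiable)
  expect_true(is.na(fc$f))
})
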