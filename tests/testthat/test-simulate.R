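# The stiff simulator: radical initialisation, integrator correctness
# against independent oracles, the acceleration event, and solver
# robustness properties.

test_that("initial radicals follow the rate-based initialisation", {
  k <- default_constants(25)
  # no hydroperoxide, no oxygen: no formation channel, all radicals zero
  cfg0 <- sim_config(c("18:2" = 1), 25, c(0, 1), tag_vial(), LOOH0 = 0,
                     O2_init = list(O2_oil = 0, O2_HS = 0))
  expect_true(all(initial_radicals(cfg0, k) == 0))
  # without Fe3+, the peroxyl pool is exactly ki*LH*O2*tau
  cfg <- sim_config(c("18:2" = 1), 25, c(0, 1), tag_vial(), LOOH0 = 10)
  rad <- initial_radicals(cfg, k)
  y <- oxikinet:::.base_state(cfg)
  ki <- get_constant(k, "ki", "18:2")
  expect_equal(rad[["LOO.18:2"]], ki * y[["LH.18:2"]] * y[["O2_oil"]] * 1)
  # second order in LOOH: doubling LOOH quadruples the bimolecular part
  kb <- rate_constant_set(matrix(1e-9, 1, 1,
                                 dimnames = list("kbimol", "18:2")),
                          enforce_fe_ratio = FALSE)
  cfg2 <- sim_config(c("18:2" = 1), 25, c(0, 1), tag_vial(), LOOH0 = 20)
  expect_equal(initial_radicals(cfg2, kb)[["LO.18:2"]],
               4 * initial_radicals(cfg, kb)[["LO.18:2"]])
})

test_that("zero kinetics give a constant trajectory", {
  cfg <- toy_config()
  traj <- simulate_oxidation(cfg, rate_constant_set())
  for (i in seq_len(nrow(traj$states)))
    expect_equal(unname(traj$states[i, ]), unname(traj$states[1, ]),
                 tolerance = 1e-10)
})

test_that("the stiff solver agrees with an explicit fixed-step RK4 oracle", {
  k <- toy_constants()
  cfg <- toy_config(t_days = seq(0, 0.25, length.out = 6),
                    rtol = 1e-10, atol = 1e-13)
  traj <- simulate_oxidation(cfg, k)

  # independent oracle: classical RK4 at a step far below the fastest
  # timescale (kp1 * O2 ~ 0.02 / s)
  p <- oxikinet:::.pack_parms(k, cfg$vial, cfg$alpha)
  y <- unname(oxikinet:::.base_state(cfg))
  rad <- initial_radicals(cfg, k)
  names(y) <- species_names()
  y[names(rad)] <- rad
  y <- unname(y)
  h <- 2
  t_end <- 0.25 * 86400
  out <- matrix(NA_real_, nrow = length(cfg$t_days), ncol = 37)
  out[1, ] <- y
  next_out <- 2
  rhs <- function(yy) oxikinet:::.rhs_r(0, yy, p)[[1]]
  for (step in seq_len(t_end / h)) {
    k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (next_out <= length(cfg$t_days) &&
        abs(step * h - cfg$t_days[next_out] * 86400) < h / 2) {
      out[next_out, ] <- y
      next_out <- next_out + 1
    }
  }
  for (j in seq_along(cfg$t_days))
    expect_rel_equal(traj$states[j, ], out[j, ], tol = 1e-6)
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  cfg <- sim_config(c("18:2" = 1), 25, t_days = seq(0, 20, length.out = 9),
                    vial = tag_vial())
  k <- default_constants(25)
  trC <- simulate_oxidation(cfg, k, compiled = TRUE)
  trR <- simulate_oxidation(cfg, k, compiled = FALSE)
  expect_rel_equal(class_totals(trC)$LOOH, class_totals(trR)$LOOH, 2e-3)
  expect_rel_equal(trC$states[9, ], trR$states[9, ], 2e-3)
})

test_that("the acceleration event switches kinetics at the crossing", {
  k <- default_constants(25)
  base_cfg <- sim_config(c("18:2" = 1), 25,
                         t_days = seq(0, 30, length.out = 61),
                         vial = tag_vial())
  base <- class_totals(simulate_oxidation(base_cfg, k))
  C_crit <- 113
  acc_cfg <- base_cfg
  acc_cfg$accel <- accel_policy(enabled = TRUE, C_crit = C_crit, f = 3)
  acc_traj <- simulate_oxidation(acc_cfg, k)
  acc <- class_totals(acc_traj)
  tc <- acc_traj$t_cross_days
  expect_true(is.finite(tc))
  # crossing is bracketed by the base run's passage through C_crit
  i_up <- which(base$LOOH >= C_crit)[1]
  expect_true(tc >= base$time_days[i_up - 1] && tc <= base$time_days[i_up])
  # before the event the two runs agree; after, the accelerated one leads
  pre <- acc$time_days < tc
  expect_rel_equal(acc$LOOH[pre], base$LOOH[pre], 1e-5)
  i_post <- which(acc$time_days > tc)[1:3]
  expect_true(all(acc$LOOH[i_post] > base$LOOH[i_post]))

  # idempotence: with f = 1 the armed event changes nothing
  id_cfg <- base_cfg
  id_cfg$accel <- accel_policy(enabled = TRUE, C_crit = C_crit, f = 1)
  expect_identical(simulate_oxidation(id_cfg, k)$states,
                   simulate_oxidation(base_cfg, k)$states)
})

test_that("oxidation accelerates with temperature", {
  ea <- default_ea_table()
  t50 <- vapply(c(25, 36.67, 48.33), function(tm) {
    cfg <- sim_config(c("18:2" = 1), tm,
                      t_days = seq(0, 120, length.out = 200),
                      vial = tag_vial())
    time_to_threshold(simulate_oxidation(cfg, constants_at_temperature(ea, tm)),
                      50)
  }, numeric(1))
  expect_true(all(is.finite(t50)))
  expect_true(all(diff(t50) < 0))
})

test_that("reported totals are tolerance-robust and non-negative", {
  k <- default_constants(25)
  cfg1 <- sim_config(c("18:2" = 1), 25, t_days = seq(0, 20, length.out = 9),
                     vial = tag_vial(), rtol = 1e-7, atol = 1e-10)
  cfg2 <- cfg1; cfg2$rtol <- 5e-8; cfg2$atol <- 5e-11
  ct1 <- class_totals(simulate_oxidation(cfg1, k))
  ct2 <- class_totals(simulate_oxidation(cfg2, k))
  for (cls in product_classes())
    expect_lt(max(abs(ct1[[cls]] - ct2[[cls]])) /
                max(ct1[[cls]], 1e-9), 1e-3)
  expect_true(all(simulate_oxidation(cfg1, k)$states >= 0))
})
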