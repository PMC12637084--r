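# The canonical reaction table, mass-action rates and the ODE right-hand
# side.

test_that("the canonical network has the expected shape and term lists", {
  net <- canonical_network()
  expect_equal(nrow(net), 23)
  antiox <- grepl("AH|A\\.", net$reactants) | net$constant %in%
    c("kAH1", "kAH2", "kAH3", "kt4", "kt5")
  expect_equal(sum(net$constant %in% c("kAH1", "kAH2", "kAH3", "kt4", "kt5")), 5)
  expect_equal(sum(!net$constant %in% c("kAH1", "kAH2", "kAH3", "kt4", "kt5")), 18)

  has <- function(col, sp) grepl(paste0("(^| )", sp, "($| |\\+)"),
                                 gsub("\\+", " + ", net[[col]]))
  # LOOH balance: consumers and producers exactly as in the hydroperoxide ODE
  consumers <- net$id[has("reactants", "LOOH")]
  expect_setequal(consumers, c("R_d", "R_pro1", "R_pro2", "R_loh2", "R_e4",
                               "R_bimol"))
  producers <- net$id[has("products", "LOOH")]
  expect_setequal(producers, c("R_p2", "R_AH1"))
  # epoxide and epoxide-hydroperoxide production channels
  expect_setequal(net$id[has("products", "EP")], c("R_e1", "R_e3"))
  expect_setequal(net$id[has("products", "EPOOH")], c("R_e2", "R_e4"))
  # every constant of the rate set is referenced exactly once
  expect_setequal(net$constant,
                  c(rownames(rate_constant_set()$perfa),
                    names(rate_constant_set()$shared)))
})

test_that("every reaction consuming LH yields a radical or regenerates LH, and radicals have sinks", {
  net <- canonical_network()
  lh_consumers <- net[grepl("LH", net$reactants), ]
  for (i in seq_len(nrow(lh_consumers)))
    expect_true(grepl("L\\.|LO\\.|LOO\\.", lh_consumers$products[i]) ||
                  lh_consumers$id[i] == "R_AH3")
  expect_true(grepl("LH", net$products[net$id == "R_AH3"]))
  # radical closure: each radical species appears as a reactant somewhere
  for (rad in c("L\\.", "LOO\\.", "LO\\.", "A\\."))
    expect_true(any(grepl(rad, net$reactants)))
})

test_that("mass-action rates follow first and second order laws", {
  k <- rate_constant_set()
  k$perfa["kpro2", ] <- 2
  k$perfa["kpro1", ] <- 2 / 100
  y <- state_init(LH = c("18:1" = 100), LOOH = 10, Fe2 = 0.001, Fe3 = 0.001)
  rr <- reaction_rates(y, k)
  r_pro2 <- rr$rate[rr$id == "R_pro2" & rr$radical_fa == "18:1"]
  expect_equal(r_pro2, 2 * 10 * 0.001)
  # constrained Fe ratio: r_pro1 / r_pro2 = 1/100 at equal iron pools
  r_pro1 <- rr$rate[rr$id == "R_pro1" & rr$radical_fa == "18:1"]
  expect_equal(r_pro1 / r_pro2, 1 / 100)
  # all-zero state: every rate vanishes
  rr0 <- reaction_rates(setNames(numeric(37), species_names()), k)
  expect_true(all(rr0$rate == 0))
  expect_error(reaction_rates(setNames(rep(-1, 37), species_names()), k),
               "negative")
})

test_that("the RHS is zero for zero kinetics in a sealed equilibrated vial", {
  k <- rate_constant_set()   # all zero
  vial <- tag_vial()
  y <- state_init(LH = c("18:2" = 1000), LOOH = 5,
                  O2_oil = vial$S_O2 * vial$p_atm_O2,
                  O2_HS = headspace_amount(vial$p_atm_O2, vial))
  d <- ode_rhs(y, k, vial)
  expect_true(all(abs(d) < 1e-14))
})

test_that("without oxygen the peroxyl derivative keeps only LOOH-derived routes", {
  k <- default_constants(25)
  vial <- tag_vial()
  y <- state_init(LH = c("18:2" = 1000), LOOH = 50, O2_oil = 2, O2_HS = 3e-5)
  y0 <- y; y0["O2_oil"] <- 0; y0["O2_HS"] <- 0
  d_with <- ode_rhs(y, k, vial)
  d_without <- ode_rhs(y0, k, vial)
  ki <- get_constant(k, "ki", "18:2")
  # the difference in LOO. production at zero radicals is exactly R_i
  expect_equal(d_with[["LOO.18:2"]] - d_without[["LOO.18:2"]],
               ki * 1000 * 2, tolerance = 1e-10)
  # LOOH-derived routes (Fe3+, and loh2/e4 pathways) persist at zero O2
  expect_gt(d_without[["LO.18:2"]], 0)
})

test_that("the acquisition correction adds exactly alpha * dLOOH/dt", {
  k <- default_constants(4)
  vial <- tag_vial()
  y <- state_init(LH = c("18:3" = 3400), LOOH = 30, O2_oil = 2, O2_HS = 3e-5)
  y[c("L.18:3", "LOO.18:3", "LO.18:3")] <- c(1e-9, 1e-6, 1e-8)
  d0 <- ode_rhs(y, k, vial, alpha_correction(enabled = FALSE))
  d1 <- ode_rhs(y, k, vial, alpha_correction(0.0018, 0.0025, enabled = TRUE))
  dlooh <- d0[["LOOH.18:3"]]
  expect_equal(d1[["ALD.18:3"]] - d0[["ALD.18:3"]], 0.0018 * dlooh,
               tolerance = 1e-12)
  expect_equal(d1[["LOH.18:3"]] - d0[["LOH.18:3"]], 0.0025 * dlooh,
               tolerance = 1e-12)
  expect_equal(d1[["LOOH.18:3"]], dlooh)
})

test_that("a two-reaction subnetwork matches hand-written mass action", {
  # only propagation (R_p2) and thermal decomposition (R_d) active
  m <- matrix(0, 18, 3, dimnames = dimnames(rate_constant_set()$perfa))
  m["kp2", "18:1"] <- 3e-3
  m["kd", "18:1"] <- 2e-6
  k <- rate_constant_set(m, enforce_fe_ratio = FALSE)
  vial <- tag_vial()
  vial$k_La <- 0; vial$P_cap <- 0
  y <- state_init(LH = c("18:1" = 500), LOOH = 20, O2_oil = 2, O2_HS = 3e-5)
  y["LOO.18:1"] <- 1e-4
  d <- ode_rhs(y, k, vial)
  r_p2 <- 3e-3 * 1e-4 * 500
  r_d <- 2e-6 * 20
  expect_equal(d[["LOOH.18:1"]], r_p2 - r_d)
  expect_equal(d[["LH.18:1"]], -r_p2)
  expect_equal(d[["L.18:1"]], r_p2)
  expect_equal(d[["LOO.18:1"]], -r_p2)
  expect_equal(d[["LO.18:1"]], r_d)
  expect_true(all(abs(d[c("ALD.18:1", "KET.18:1", "EP.18:1")]) == 0))
})

test_that("lipid units balance along a simulated trajectory", {
  des <- preset_design("trilinolein")
  cfg <- sim_config(c("18:2" = 1), 25, t_days = seq(0, 30, length.out = 7),
                    vial = tag_vial(), rtol = 1e-10, atol = 1e-12)
  mb <- mass_balance(simulate_oxidation(cfg, default_constants(25)))
  expect_equal(mb$flag, "ok")
  expect_lt(abs(mb$fraction - 1), 1e-6)
  # truncated mid-induction: the balance still closes
  cfg2 <- sim_config(c("18:2" = 1), 25, t_days = c(0, 2, 4),
                     vial = tag_vial(), rtol = 1e-10, atol = 1e-12)
  mb2 <- mass_balance(simulate_oxidation(cfg2, default_constants(25)))
  expect_lt(abs(mb2$fraction - 1), 1e-6)
  # zero conversion is flagged, not scored
  cfg0 <- toy_config()
  mb0 <- mass_balance(simulate_oxidation(cfg0, rate_constant_set()))
  expect_equal(mb0$flag, "no conversion")
  expect_true(is.na(mb0$fraction))
})
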