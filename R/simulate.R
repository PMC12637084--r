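# Stiff integration of the full network over a storage horizon, with
# rate-based radical initialisation and the optional critical-hydroperoxide
# acceleration event.

# mean fatty-acyl residue molar masses (g/mol) for converting oil mass to
# residue concentration; saturated = palmitic/stearic-dominated average
.RESIDUE_MW <- c("18:1" = 282.46, "18:2" = 280.45, "18:3" = 278.43,
                 saturated = 265.0)

#' Critical-hydroperoxide acceleration policy
#'
#' Above a critical total LOOH concentration, colloidal structuring of
#' the oil accelerates oxidation; the model captures this
#' phenomenologically by switching the rate constants to `f * k` at the
#' crossing (detected as an integration event).
#'
#' @param enabled Whether the event is armed.
#' @param C_crit Critical total LOOH concentration (mmol/kg).
#' @param f Acceleration factor (scalar, or named per-constant vector;
#'   see [apply_acceleration()]).
#' @param constants Constants a scalar `f` applies to.
#' @return An object of class `ox_accel`.
#' @export
accel_policy <- function(enabled = FALSE, C_crit = NA_real_, f = 1,
                         constants = c("kd", "kpro1", "kpro2", "kbimol",
                                       "kloh2", "ke4", "kp2", "kp1")) {
  if (isTRUE(enabled) && (!is.finite(C_crit) || C_crit <= 0))
    stop("an enabled acceleration policy needs a positive C_crit")
  structure(list(enabled = isTRUE(enabled), C_crit = C_crit, f = f,
                 constants = constants), class = "ox_accel")
}

#' Configure a storage-oxidation simulation
#'
#' @param composition Named mole fractions over `"18:1"`, `"18:2"`,
#'   `"18:3"` and optionally `"saturated"` (inert); must sum to 1 within
#'   1e-9.
#' @param temperature_C Storage temperature (degrees Celsius).
#' @param t_days Output time grid in days, strictly increasing from 0.
#' @param vial An `ox_vial`; its temperature is set to `temperature_C`.
#' @param LOOH0 Initial hydroperoxide concentration (mmol/kg), split over
#'   the unsaturated fatty acids by mole fraction.
#' @param products0 Named initial product-class concentrations
#'   (`ALD`, `KET`, `LOH`, `EP`, `EPOOH`), default all zero.
#' @param AH0 Initial antioxidant (tocopherol) concentration (mmol/kg).
#' @param Fe2_0,Fe3_0 Initial ferrous/ferric iron (mmol/kg).
#' @param O2_init `"air"` (dissolved oxygen at air saturation, headspace
#'   at ambient partial pressure) or a list with `O2_oil` (mmol/kg) and
#'   `O2_HS` (mol).
#' @param alpha An [alpha_correction()]; enable for trilinolenin only.
#' @param accel An [accel_policy()].
#' @param rtol,atol Solver tolerances.
#' @param tau Rate-to-concentration carrier (s) for the radical
#'   initialisation (see [initial_radicals()]).
#' @param residue_mmol_per_kg Total fatty-acyl residue concentration;
#'   computed from the composition and residue molar masses when `NULL`.
#' @return An object of class `ox_config`.
#' @export
sim_config <- function(composition, temperature_C, t_days, vial,
                       LOOH0 = 1, products0 = NULL, AH0 = 0,
                       Fe2_0 = 0, Fe3_0 = 0, O2_init = "air",
                       alpha = alpha_correction(), accel = accel_policy(),
                       rtol = 1e-7, atol = 1e-10, tau = 1,
                       residue_mmol_per_kg = NULL) {
  stopifnot(inherits(vial, "ox_vial"), inherits(alpha, "ox_alpha"),
            inherits(accel, "ox_accel"))
  bad <- setdiff(names(composition), names(.RESIDUE_MW))
  if (length(bad)) stop("unknown composition component(s): ",
                        paste(bad, collapse = ", "))
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition mole fractions must sum to 1")
  if (any(composition < 0)) stop("composition fractions must be non-negative")
  t_days <- as.numeric(t_days)
  if (t_days[1] != 0 || any(diff(t_days) <= 0))
    stop("t_days must be strictly increasing from 0")
  if (is.null(residue_mmol_per_kg)) {
    comp_full <- setNames(numeric(length(.RESIDUE_MW)), names(.RESIDUE_MW))
    comp_full[names(composition)] <- composition
    mw_tag <- 3 * sum(comp_full * .RESIDUE_MW) + 38.05
    residue_mmol_per_kg <- 3e6 / mw_tag
  }
  prod0 <- setNames(numeric(5), c("ALD", "KET", "LOH", "EP", "EPOOH"))
  if (!is.null(products0)) {
    bad <- setdiff(names(products0), names(prod0))
    if (length(bad)) stop("unknown product class(es): ",
                          paste(bad, collapse = ", "))
    prod0[names(products0)] <- products0
  }
  vial$T <- temperature_C + 273.15
  structure(list(composition = composition, temperature_C = temperature_C,
                 t_days = t_days, vial = vial, LOOH0 = LOOH0,
                 products0 = prod0, AH0 = AH0, Fe2_0 = Fe2_0,
                 Fe3_0 = Fe3_0, O2_init = O2_init, alpha = alpha,
                 accel = accel, rtol = rtol, atol = atol, tau = tau,
                 residue_mmol_per_kg = residue_mmol_per_kg),
            class = "ox_config")
}

# state vector before radical initialisation
.base_state <- function(config) {
  fas <- intersect(names(config$composition), fatty_acids())
  lh <- config$composition[fas] * config$residue_mmol_per_kg
  if (identical(config$O2_init, "air")) {
    o2_oil <- config$vial$S_O2 * config$vial$p_atm_O2
    o2_hs <- headspace_amount(config$vial$p_atm_O2, config$vial)
  } else {
    o2_oil <- config$O2_init$O2_oil
    o2_hs <- config$O2_init$O2_HS
  }
  state_init(LH = lh, LOOH = config$LOOH0,
             ALD = config$products0[["ALD"]], KET = config$products0[["KET"]],
             LOH = config$products0[["LOH"]], EP = config$products0[["EP"]],
             EPOOH = config$products0[["EPOOH"]], AH = config$AH0,
             Fe2 = config$Fe2_0, Fe3 = config$Fe3_0,
             O2_oil = o2_oil, O2_HS = o2_hs)
}

#' Rate-based initial radical concentrations
#'
#' The initial radical pools are taken equal to their formation rates at
#' t0 times a unit carrier `tau` (default 1 s): the peroxyl pool from the
#' initiation and Fe3+ channels, the alkoxyl pool from the thermal, Fe2+
#' and bimolecular hydroperoxide decomposition channels; the alkyl pool
#' starts at zero (no initiation channel produces it directly).
#'
#' @param config An `ox_config`.
#' @param k An `ox_constants`.
#' @return Named vector of initial `L`, `LOO`, `LO` concentrations per
#'   fatty acid (mmol/kg).
#' @export
initial_radicals <- function(config, k) {
  y <- .base_state(config)
  fas <- fatty_acids()
  out <- c()
  for (fa in fas) {
    lh <- y[paste("LH", fa, sep = ".")]
    looh <- y[paste("LOOH", fa, sep = ".")]
    loo <- (get_constant(k, "ki", fa) * lh * y[["O2_oil"]] +
            get_constant(k, "kpro1", fa) * y[["Fe3"]] * looh) * config$tau
    lo <- (get_constant(k, "kd", fa) * looh +
           get_constant(k, "kpro2", fa) * y[["Fe2"]] * looh +
           get_constant(k, "kbimol", fa) * looh^2) * config$tau
    out <- c(out, setNames(c(0, loo, lo),
                           paste(c("L", "LOO", "LO"), fa, sep = ".")))
  }
  out
}

# one solver leg: BDF (vode, internally generated full Jacobian), the
# workhorse for this stiff radical/mass-transfer system
.integrate_leg <- function(y0, times_s, parms, rtol, atol, compiled) {
  if (compiled) {
    deSolve::vode(y = y0, times = times_s, func = "ox_derivs",
                  parms = parms, dllname = "oxikinet",
                  initfunc = "ox_initmod", rtol = rtol, atol = atol,
                  mf = 22, maxsteps = 100000)
  } else {
    deSolve::vode(y = y0, times = times_s,
                  func = function(t, y, p) .rhs_r(t, y, p), parms = parms,
                  rtol = rtol, atol = atol, mf = 22, maxsteps = 100000)
  }
}

#' Simulate a storage-oxidation experiment
#'
#' Integrates the full network with a stiff BDF solver. When the
#' acceleration event is armed, the crossing of the total LOOH
#' concentration through `C_crit` is located exactly (bracketing on the
#' output grid, then bisection with re-integration) and the constants
#' switch to `f * k` for the remainder of the horizon.
#'
#' @param config An `ox_config`.
#' @param k An `ox_constants` covering the fatty acids present.
#' @param compiled Use the compiled right-hand side (default); the pure-R
#'   transliteration is available for checking.
#' @return An `ox_trajectory`: sampled states on the configured grid,
#'   per-class totals, and solver diagnostics (including the event
#'   crossing time, if any).
#' @export
simulate_oxidation <- function(config, k, compiled = TRUE) {
  stopifnot(inherits(config, "ox_config"), inherits(k, "ox_constants"))
  y0 <- .base_state(config)
  rad <- initial_radicals(config, k)
  y0[names(rad)] <- rad
  times_s <- config$t_days * 86400
  accel <- config$accel
  use_event <- accel$enabled &&
    !(length(accel$f) == 1L && is.null(names(accel$f)) && accel$f == 1)
  parms <- .pack_parms(k, config$vial, config$alpha)
  troot <- NA_real_

  run <- function(y, tt, p) {
    out <- withCallingHandlers(
      .integrate_leg(y, tt, p, config$rtol, config$atol, compiled),
      warning = function(w) invokeRestart("muffleWarning"))
    istate <- attr(out, "istate")[1]
    if (!is.null(istate) && istate < 0)
      stop(sprintf("solver failure (istate %d) at t = %.6g days",
                   istate, max(out[, 1]) / 86400))
    out
  }
  looh_total <- function(row) sum(row[1 + c(5, 15, 25)])

  if (!use_event) {
    out <- run(y0, times_s, parms)
  } else if (sum(y0[paste("LOOH", fatty_acids(), sep = ".")]) >= accel$C_crit) {
    # already beyond the threshold: accelerated from the start
    troot <- 0
    k2 <- apply_acceleration(k, accel$f, accel$constants)
    out <- run(y0, times_s, .pack_parms(k2, config$vial, config$alpha))
  } else {
    out1 <- run(y0, times_s, parms)
    cross <- which(apply(out1, 1, looh_total) >= accel$C_crit)
    if (!length(cross)) {
      out <- out1
    } else {
      # bracket the crossing between grid points, then bisect by short
      # re-integrations from the last sub-threshold state
      i <- cross[1]
      t_lo <- out1[i - 1, 1]
      y_lo <- as.numeric(out1[i - 1, -1])
      t_hi <- out1[i, 1]
      for (it in 1:60) {
        if (t_hi - t_lo <= max(1e-3, 1e-10 * times_s[length(times_s)])) break
        t_mid <- (t_lo + t_hi) / 2
        probe <- run(y_lo, c(t_lo, t_mid), parms)
        if (looh_total(probe[2, ]) >= accel$C_crit) {
          t_hi <- t_mid
        } else {
          t_lo <- t_mid
          y_lo <- as.numeric(probe[2, -1])
        }
      }
      troot <- t_hi
      y_ev <- as.numeric(run(y_lo, c(t_lo, troot), parms)[2, -1])
      k2 <- apply_acceleration(k, accel$f, accel$constants)
      p2 <- .pack_parms(k2, config$vial, config$alpha)
      keep1 <- out1[out1[, 1] < troot, , drop = FALSE]
      t2 <- times_s[times_s >= troot]
      if (length(t2)) {
        out2 <- run(y_ev, unique(c(troot, t2)), p2)
        out <- rbind(keep1, out2[out2[, 1] %in% times_s, , drop = FALSE])
      } else {
        out <- keep1
      }
    }
  }

  states <- out[, -1, drop = FALSE]
  colnames(states) <- species_names()
  too_neg <- states < -1e-4
  if (any(too_neg)) {
    bad <- colnames(states)[which(apply(too_neg, 2, any))[1]]
    stop("negative-state excursion beyond tolerance for species ", bad)
  }
  states[states < 0] <- 0
  t_days <- out[, 1] / 86400

  totals <- data.frame(time_days = t_days)
  for (cls in product_classes())
    totals[[cls]] <- rowSums(states[, paste(cls, fatty_acids(), sep = "."),
                                    drop = FALSE])
  totals$AH <- states[, "AH"]
  totals$O2_oil <- states[, "O2_oil"]
  totals$O2_HS <- states[, "O2_HS"]

  structure(list(times_s = t_days * 86400, times_days = t_days,
                 states = states, class_totals = totals,
                 t_cross_days = troot / 86400,
                 config = config, k = k, alpha = config$alpha),
            class = "ox_trajectory")
}

#' @export
print.ox_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Oxidation trajectory: %d time points over %.3g days at %.1f degC\n",
              n, max(x$times_days), x$config$temperature_C))
  final <- x$class_totals[n, product_classes()]
  cat("final class totals (mmol/kg):\n")
  print(round(unlist(final), 2))
  if (is.finite(x$t_cross_days))
    cat(sprintf("acceleration event at %.2f days\n", x$t_cross_days))
  invisible(x)
}

#' Per-class totals of a trajectory
#'
#' @param traj An `ox_trajectory`.
#' @return Data frame with `time_days`, one column per product class
#'   (summed over fatty acids), plus `AH`, `O2_oil` and `O2_HS`.
#' @export
class_totals <- function(traj) {
  stopifnot(inherits(traj, "ox_trajectory"))
  traj$class_totals
}

#' @export
as.data.frame.ox_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  sp <- rep(sub("\\..*$", "", species_names()), times = n)
  fa <- rep(sub("^[^.]*\\.?", "", species_names()), times = n)
  data.frame(time_days = rep(x$times_days, each = ncol(x$states)),
             species = sp,
             fatty_acid = ifelse(fa == "", NA, fa),
             concentration = as.vector(t(x$states)))
}

#' Time at which a product class crosses a threshold
#'
#' Linear interpolation on the sampled class totals.
#'
#' @param traj An `ox_trajectory`.
#' @param threshold Concentration threshold (mmol/kg).
#' @param class Product class (default `"LOOH"`).
#' @return Crossing time in days, or `NA` if never reached.
#' @export
time_to_threshold <- function(traj, threshold, class = "LOOH") {
  ct <- class_totals(traj)
  y <- ct[[class]]
  if (all(y < threshold)) return(NA_real_)
  i <- which(y >= threshold)[1]
  if (i == 1) return(ct$time_days[1])
  t0 <- ct$time_days[i - 1]; t1 <- ct$time_days[i]
  y0 <- y[i - 1]; y1 <- y[i]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}
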