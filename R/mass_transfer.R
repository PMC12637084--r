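# Two-phase (oil + headspace) oxygen bookkeeping: film-model dissolution at
# the oil surface, linear permeation through the cap, and the conversion
# helpers between headspace amount, partial pressure and dissolved
# concentration.

#' Describe a two-phase oil/headspace vial system
#'
#' @param V_HS Headspace volume (m^3).
#' @param V_oil Oil volume (m^3).
#' @param A_int Oil-headspace interface area (m^2).
#' @param oil_mass Oil mass (kg).
#' @param k_La Interfacial mass-transfer coefficient (m/s). The default
#'   1e-5 m/s is a literature-style film coefficient for an unstirred
#'   oil surface.
#' @param S_O2 Oxygen solubility in oil (mmol kg^-1 atm^-1); the default
#'   10 gives about 2.1 mmol/kg dissolved oxygen under air, in the range
#'   reported for vegetable oils.
#' @param P_cap Cap permeation coefficient (mol s^-1 atm^-1); 0 for an
#'   air-tight stopper.
#' @param T Temperature (K), used for the ideal-gas headspace pressure.
#' @param p_atm_O2 Ambient oxygen partial pressure (atm).
#' @return An object of class `ox_vial`.
#' @export
vial_system <- function(V_HS, V_oil, A_int, oil_mass, k_La = 1e-5,
                        S_O2 = 10, P_cap = 0, T = 293.15, p_atm_O2 = 0.21) {
  if (V_HS <= 0 || V_oil <= 0 || A_int <= 0 || oil_mass <= 0)
    stop("vial volumes, interface area and oil mass must be positive")
  stopifnot(k_La >= 0, S_O2 >= 0, P_cap >= 0, T > 0)
  structure(list(V_HS = V_HS, V_oil = V_oil, A_int = A_int,
                 oil_mass = oil_mass, k_La = k_La, S_O2 = S_O2,
                 P_cap = P_cap, T = T, p_atm_O2 = p_atm_O2),
            class = "ox_vial")
}

#' @export
print.ox_vial <- function(x, ...) {
  cat(sprintf(paste0("Vial: %.2f mL headspace, %.2f mL oil (%.3g g), ",
                     "interface %.2f cm2\n"),
              x$V_HS * 1e6, x$V_oil * 1e6, x$oil_mass * 1e3, x$A_int * 1e4))
  cat(sprintf("  oil column height %.2f mm, k_La %.2g m/s, S_O2 %.3g mmol/kg/atm, P_cap %.2g mol/s/atm, T %.1f K\n",
              x$V_oil / x$A_int * 1e3, x$k_La, x$S_O2, x$P_cap, x$T))
  invisible(x)
}

#' Construct a vial system from its geometry
#'
#' Computes the interface area from the internal diameter (circular
#' cross-section) and the headspace volume as the internal volume minus
#' the oil volume.
#'
#' @param internal_volume Vial internal volume (m^3).
#' @param internal_diameter Vial internal diameter (m).
#' @param oil_volume Oil volume (m^3); must be smaller than the internal
#'   volume.
#' @param oil_density Oil density (kg/m^3).
#' @param ... Passed on to [vial_system()] (`k_La`, `S_O2`, `P_cap`, `T`,
#'   `p_atm_O2`).
#' @return An `ox_vial` object.
#' @export
vial_from_geometry <- function(internal_volume, internal_diameter,
                               oil_volume, oil_density = 915, ...) {
  if (oil_volume >= internal_volume)
    stop("geometry error: oil volume must be smaller than the vial volume")
  A <- pi * (internal_diameter / 2)^2
  vial_system(V_HS = internal_volume - oil_volume, V_oil = oil_volume,
              A_int = A, oil_mass = oil_volume * oil_density, ...)
}

#' Headspace oxygen partial pressure from amount
#'
#' Ideal-gas conversion at the vial temperature.
#'
#' @param n_O2 Headspace oxygen amount (mol).
#' @param vial An `ox_vial`.
#' @return Partial pressure (atm).
#' @export
headspace_pressure <- function(n_O2, vial) {
  n_O2 * .RGAS_ATM * vial$T / vial$V_HS
}

#' Headspace oxygen amount at a given partial pressure
#'
#' @param p_O2 Oxygen partial pressure (atm).
#' @param vial An `ox_vial`.
#' @return Amount (mol).
#' @export
headspace_amount <- function(p_O2, vial) {
  p_O2 * vial$V_HS / (.RGAS_ATM * vial$T)
}

#' Instantaneous oxygen fluxes of the two-phase system
#'
#' The interfacial flux follows a linear driving force towards the
#' solubility equilibrium with the current headspace pressure
#' (`phi_s > 0` means headspace to oil); cap permeation follows the
#' pressure difference to the ambient atmosphere; the reactive flux is
#' the oil-phase oxygen consumption converted to mol/s.
#'
#' @param O2_oil Dissolved oxygen (mmol/kg).
#' @param O2_HS Headspace oxygen amount (mol).
#' @param vial An `ox_vial`.
#' @param reactive_rate Oil-phase oxygen consumption rate
#'   (mmol kg^-1 s^-1, non-negative).
#' @return A list with `phi_s`, `phi_Pe`, `phi_oil` (mol/s), the
#'   headspace derivative `dO2_HS` (mol/s) and the dissolved-oxygen
#'   derivative `dO2_oil` (mmol kg^-1 s^-1).
#' @export
o2_fluxes <- function(O2_oil, O2_HS, vial, reactive_rate = 0) {
  stopifnot(O2_oil >= 0, O2_HS >= 0, reactive_rate >= 0)
  pHS <- headspace_pressure(O2_HS, vial)
  phi_s <- vial$k_La * vial$A_int * (vial$S_O2 * pHS - O2_oil) *
    vial$oil_mass / vial$V_oil / 1000
  phi_Pe <- vial$P_cap * (vial$p_atm_O2 - pHS)
  phi_oil <- -reactive_rate * vial$oil_mass / 1000
  list(phi_s = phi_s, phi_Pe = phi_Pe, phi_oil = phi_oil,
       dO2_HS = phi_Pe - phi_s,
       dO2_oil = phi_s * 1000 / vial$oil_mass - reactive_rate)
}

#' Closed-form two-compartment oxygen equilibrium
#'
#' For a sealed vial with no reaction, the dissolved concentration relaxes
#' to the solubility equilibrium with the headspace under conservation of
#' total oxygen; this returns that fixed point.
#'
#' @param n_total Total oxygen amount (headspace + dissolved, mol).
#' @param vial An `ox_vial`.
#' @return A list with the equilibrium dissolved concentration `O2_oil`
#'   (mmol/kg), headspace amount `O2_HS` (mol) and pressure `p_HS` (atm).
#' @export
o2_equilibrium <- function(n_total, vial) {
  a <- vial$S_O2 * .RGAS_ATM * vial$T / vial$V_HS  # (mmol/kg) per mol in HS
  c_eq <- a * n_total / (1 + a * vial$oil_mass / 1000)
  n_hs <- n_total - c_eq * vial$oil_mass / 1000
  list(O2_oil = c_eq, O2_HS = n_hs, p_HS = headspace_pressure(n_hs, vial))
}
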