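# Arrhenius temperature parametrisation and the cross-kinetic mixing rules
# that extend pure-TAG constants to fatty-acid blends.

# how each constant resolves for a cross-fatty-acid encounter
.MIX_RULE <- c(
  ki = "self", kp1 = "self", kd = "self", kpro1 = "self", kpro2 = "self",
  kp2 = "donor", kald = "donor", kket = "donor", kloh1 = "donor",
  kloh2 = "donor", ke2 = "donor",
  ke4 = "hydroperoxide",
  ke1 = "radical", ke3 = "radical",
  kbimol = "geometric", kt1 = "geometric", kt2 = "geometric",
  kt3 = "geometric"
)

#' Mixing rule of each per-fatty-acid constant
#'
#' Hydrogen-abstraction constants depend on the hydrogen donor, not on the
#' abstracting radical, so they resolve by the partner (`donor`); the
#' peroxyl addition on a hydroperoxide resolves by the hydroperoxide
#' species; the cyclisation channels `ke1`/`ke3` resolve by the radical
#' species; constants the mixture scheme leaves open (`kbimol`, the
#' recombinations) use the geometric mean of the two per-fatty-acid
#' values.
#'
#' @return Named character vector mapping constant name to rule.
#' @export
mix_rule <- function() .MIX_RULE

#' Resolve a kinetic constant for a cross-fatty-acid reaction instance
#'
#' @param constant Per-fatty-acid constant name (or a shared antioxidant
#'   constant, returned as is).
#' @param radical_fa Fatty acid of the attacking radical.
#' @param partner_fa Fatty acid of the reaction partner (hydrogen donor,
#'   hydroperoxide, or second radical).
#' @param k An `ox_constants` object.
#' @return The resolved numeric constant. Self pairs reduce to the plain
#'   per-fatty-acid value for every rule.
#' @export
resolve_cross_constant <- function(constant, radical_fa, partner_fa, k) {
  stopifnot(inherits(k, "ox_constants"))
  if (constant %in% .K_SHARED) return(unname(k$shared[constant]))
  rule <- .MIX_RULE[constant]
  if (is.na(rule)) stop("unknown constant: ", constant)
  switch(rule,
         donor = ,
         hydroperoxide = unname(k$perfa[constant, partner_fa]),
         radical = ,
         self = unname(k$perfa[constant, radical_fa]),
         geometric = unname(sqrt(k$perfa[constant, radical_fa] *
                                 k$perfa[constant, partner_fa])))
}

#' Estimate an activation energy from per-temperature constants
#'
#' Fits the log-linear Arrhenius relation
#' `ln(k/k_ref) = Ea/R * (1/T_ref - 1/T)` by least squares, taking the
#' lowest supplied incubation temperature as the reference.
#'
#' @param k Positive kinetic constants, one per temperature.
#' @param temp_C Matching temperatures (degrees Celsius).
#' @return A list with `Ea_kJ_per_mol`, `k_ref` (the constant at the
#'   reference temperature) and `T_ref_C`.
#' @export
estimate_ea <- function(k, temp_C) {
  if (length(k) != length(temp_C)) stop("k and temp_C lengths differ")
  if (length(k) < 2) stop("insufficient data: need constants at >= 2 temperatures")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all kinetic constants must be positive")
  o <- order(temp_C)
  k <- k[o]; temp_C <- temp_C[o]
  T_K <- temp_C + 273.15
  T_ref <- T_K[1]
  y <- log(k / k[1])
  x <- (1 / T_ref - 1 / T_K) / .RGAS_J        # so y = Ea[J/mol] * x
  Ea <- if (all(abs(x) < 1e-15)) 0 else sum(x * y) / sum(x * x)
  list(Ea_kJ_per_mol = Ea / 1000, k_ref = unname(k[1]), T_ref_C = temp_C[1])
}

#' Evaluate the Arrhenius law at a temperature
#'
#' `k(T) = k_ref * exp(-Ea/R * (1/T - 1/T_ref))`; the inverse of
#' [estimate_ea()].
#'
#' @param temp_C Temperature(s) in degrees Celsius.
#' @param Ea_kJ_per_mol Activation energy (kJ/mol); `NA` marks an entry
#'   with no temperature dependence available and is an error here.
#' @param k_ref Constant at the reference temperature.
#' @param T_ref_C Reference temperature (degrees Celsius).
#' @return Constant(s) at `temp_C`.
#' @export
k_at <- function(temp_C, Ea_kJ_per_mol, k_ref, T_ref_C) {
  if (any(is.na(Ea_kJ_per_mol)))
    stop("activation energy unavailable (n.d. entry); cannot interpolate")
  stopifnot(all(temp_C > -273.15))
  k_ref * exp(-(Ea_kJ_per_mol * 1000) / .RGAS_J *
                (1 / (temp_C + 273.15) - 1 / (T_ref_C + 273.15)))
}

#' Construct an Arrhenius parameter table
#'
#' One row per (constant, fatty acid): activation energy, reference
#' constant and reference temperature. Entries with `Ea_kJ_per_mol = NA`
#' are "n.d." (not determined, typically because the model output is
#' insensitive to them); [constants_at_temperature()] holds those at
#' `k_ref` instead of extrapolating.
#'
#' @param constant,fatty_acid,Ea_kJ_per_mol,k_ref,T_ref_C Column vectors.
#' @return A data.frame of class `ox_ea_table`.
#' @export
arrhenius_table <- function(constant, fatty_acid, Ea_kJ_per_mol, k_ref,
                            T_ref_C) {
  stopifnot(all(fatty_acid %in% fatty_acids()),
            all(constant %in% .K_PERFA),
            all(k_ref >= 0), all(T_ref_C > -273.15))
  out <- data.frame(constant = constant, fatty_acid = fatty_acid,
                    Ea_kJ_per_mol = Ea_kJ_per_mol, k_ref = k_ref,
                    T_ref_C = T_ref_C, stringsAsFactors = FALSE)
  class(out) <- c("ox_ea_table", class(out))
  out
}

#' Interpolate a full constant set to a storage temperature
#'
#' Applies [k_at()] to every available row of an Arrhenius table; n.d.
#' rows (missing activation energy) fall back to their reference value,
#' i.e. are treated as temperature independent, with a warning.
#'
#' @param ea_table An `ox_ea_table`.
#' @param temp_C Target temperature (degrees Celsius).
#' @param shared Named vector of shared antioxidant constants (treated as
#'   temperature independent).
#' @param warn_nd Warn when n.d. entries are held at their reference
#'   value.
#' @return An `ox_constants` object.
#' @export
constants_at_temperature <- function(ea_table, temp_C, shared = NULL,
                                     warn_nd = FALSE) {
  stopifnot(inherits(ea_table, "ox_ea_table"), length(temp_C) == 1L)
  m <- matrix(0, nrow = length(.K_PERFA), ncol = 3,
              dimnames = list(.K_PERFA, fatty_acids()))
  nd <- character(0)
  for (i in seq_len(nrow(ea_table))) {
    row <- ea_table[i, ]
    if (is.na(row$Ea_kJ_per_mol)) {
      m[row$constant, row$fatty_acid] <- row$k_ref
      nd <- c(nd, paste0(row$constant, "(", row$fatty_acid, ")"))
    } else {
      m[row$constant, row$fatty_acid] <-
        k_at(temp_C, row$Ea_kJ_per_mol, row$k_ref, row$T_ref_C)
    }
  }
  if (warn_nd && length(nd))
    warning("held at reference value (no activation energy): ",
            paste(nd, collapse = ", "))
  rate_constant_set(perfa = m, shared = shared)
}

#' Estimate activation energies for all constants of a fitted series
#'
#' Convenience wrapper: given per-temperature constant estimates for one
#' fatty acid, runs [estimate_ea()] per constant.
#'
#' @param k_by_temp Numeric matrix of constants, rows named by constant,
#'   columns by temperature (degrees Celsius, coercible via
#'   `as.numeric(colnames(...))`).
#' @param fatty_acid Fatty-acid label recorded in the result.
#' @return An `ox_ea_table`.
#' @export
estimate_ea_table <- function(k_by_temp, fatty_acid) {
  temps <- as.numeric(colnames(k_by_temp))
  rows <- lapply(rownames(k_by_temp), function(cn) {
    kk <- k_by_temp[cn, ]
    if (any(!is.finite(kk)) || any(kk <= 0))
      return(data.frame(constant = cn, fatty_acid = fatty_acid,
                        Ea_kJ_per_mol = NA_real_, k_ref = NA_real_,
                        T_ref_C = min(temps)))
    est <- estimate_ea(kk, temps)
    data.frame(constant = cn, fatty_acid = fatty_acid,
               Ea_kJ_per_mol = est$Ea_kJ_per_mol, k_ref = est$k_ref,
               T_ref_C = est$T_ref_C)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ox_ea_table", class(out))
  out
}
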