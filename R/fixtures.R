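# Shipped parameter fixtures. The activation energies are the
# literature-anchored per-fatty-acid values; the reference constants are a
# synthetic, order-of-magnitude-plausible set (files labelled "_synthetic")
# calibrated once so that simulated curves span realistic concentration
# ranges (LOOH up to hundreds of mmol/kg, secondary products tens).

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "oxikinet")
  if (!nzchar(path)) stop("fixture file not found: ", file)
  path
}

#' Shipped Arrhenius reference table
#'
#' Activation energies per (constant, fatty acid) with synthetic reference
#' constants at each substrate's lowest incubation temperature (40, 25 and
#' 4 degrees C for the 18:1, 18:2 and 18:3 model triacylglycerols).
#' Entries without an activation energy (insensitive constants or
#' low-concentration products) are n.d. and fall back to their reference
#' value on interpolation.
#'
#' @return An `ox_ea_table`.
#' @export
default_ea_table <- function() {
  read_ea_table(.extdata("arrhenius_synthetic.tsv"))
}

#' Shipped shared antioxidant constants
#'
#' Synthetic tocopherol scavenging/termination constants of plausible
#' magnitude (hydrogen donation to peroxyl radicals near the
#' diffusion-influenced regime, slower donation to alkoxyl and alkyl
#' radicals), treated as temperature independent.
#'
#' @return Named numeric vector (`kAH1`, `kAH2`, `kAH3`, `kt4`, `kt5`).
#' @export
default_shared_constants <- function() {
  df <- read.delim(.extdata("shared_constants_synthetic.tsv"))
  setNames(df$value, df$constant)
}

#' Shipped ground-truth constants at a storage temperature
#'
#' Interpolates the shipped Arrhenius table to `temp_C` (n.d. entries held
#' at their reference values) and attaches the shared antioxidant
#' constants. This is the generating truth used by the synthetic-data
#' presets.
#'
#' @param temp_C Storage temperature (degrees Celsius).
#' @return An `ox_constants`.
#' @export
default_constants <- function(temp_C) {
  constants_at_temperature(default_ea_table(), temp_C,
                           shared = default_shared_constants())
}

#' Literature-style starting values for optimisation
#'
#' A deliberately coarse (one-significant-figure, partly displaced)
#' version of the shipped reference constants, playing the role of
#' literature starting values for the multistart fits.
#'
#' @param temp_C Temperature at which starting constants are produced.
#' @return An `ox_constants`.
#' @export
default_start_constants <- function(temp_C) {
  k <- default_constants(temp_C)
  k$perfa <- signif(k$perfa * 2, 1)
  k$perfa["kpro1", ] <- k$perfa["kpro2", ] / 100
  k$shared <- signif(k$shared * 2, 1)
  k
}
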