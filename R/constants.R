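# Species layout and rate-constant containers. The state vector always uses
# the fixed three-fatty-acid layout (absent fatty acids carry zeros), which
# keeps the compiled RHS branch-free and the indexing identical everywhere.

#' Fatty-acid classes tracked by the network
#'
#' The network resolves the unsaturated fatty acids of common vegetable
#' oils: oleic ("18:1"), linoleic ("18:2") and alpha-linolenic ("18:3")
#' residues. Saturated fat is carried as an inert mole fraction, not a
#' species.
#'
#' @return Character vector of the three class labels.
#' @export
fatty_acids <- function() c("18:1", "18:2", "18:3")

# per-fatty-acid species blocks, in state-vector order
.SPECIES_FA <- c("LH", "L", "LOO", "LO", "LOOH",
                 "ALD", "KET", "LOH", "EP", "EPOOH")
.SPECIES_SHARED <- c("AH", "A", "Fe2", "Fe3", "O2_oil", "O2_HS", "NRP")
.PRODUCT_CLASSES <- c("LOOH", "ALD", "KET", "LOH", "EP", "EPOOH")

# per-fatty-acid constants, in the order of the packed parameter vector
.K_PERFA <- c("ki", "kp1", "kp2", "kd", "kbimol", "kpro1", "kpro2",
              "ke1", "ke2", "ke3", "ke4", "kald", "kket", "kloh1", "kloh2",
              "kt1", "kt2", "kt3")
.K_SHARED <- c("kAH1", "kAH2", "kAH3", "kt4", "kt5")

#' Names of the state-vector entries
#'
#' Per-fatty-acid species are named `"<species>.<fatty acid>"`
#' (e.g. `"LOOH.18:2"`); shared pools keep their plain names. `O2_oil` is
#' dissolved oxygen (mmol/kg oil), `O2_HS` the headspace oxygen amount
#' (mol), and `NRP` the cumulative lipid units lost to non-radical
#' termination products (a bookkeeping sink used by [mass_balance()]).
#'
#' @return Character vector of length 37.
#' @export
species_names <- function() {
  c(as.vector(vapply(fatty_acids(),
                     function(fa) paste(.SPECIES_FA, fa, sep = "."),
                     character(length(.SPECIES_FA)))),
    .SPECIES_SHARED)
}

#' Product classes quantified by the NMR platform
#'
#' @return Character vector: LOOH, ALD, KET, LOH, EP, EPOOH.
#' @export
product_classes <- function() .PRODUCT_CLASSES

#' Construct a set of kinetic rate constants
#'
#' Holds the per-fatty-acid constants of the 18 lipid reactions plus the
#' five shared antioxidant constants. Units: `kd` is first order (1/s);
#' all other constants are second order (kg mmol^-1 s^-1).
#'
#' @param perfa Numeric matrix, rows named by the per-fatty-acid constants
#'   (`ki`, `kp1`, `kp2`, `kd`, `kbimol`, `kpro1`, `kpro2`, `ke1`--`ke4`,
#'   `kald`, `kket`, `kloh1`, `kloh2`, `kt1`--`kt3`), columns by
#'   [fatty_acids()]. Missing rows/columns are filled with zero.
#' @param shared Named numeric vector of the antioxidant constants
#'   `kAH1`, `kAH2`, `kAH3`, `kt4`, `kt5`; missing entries default to 0.
#' @param enforce_fe_ratio If `TRUE` (default), the Fe3+ channel is tied
#'   to the Fe2+ channel as `kpro1 = kpro2 / 100` (model assumption that
#'   removes a redundant parameter).
#' @return An object of class `ox_constants`.
#' @export
rate_constant_set <- function(perfa = NULL, shared = NULL,
                              enforce_fe_ratio = TRUE) {
  m <- matrix(0, nrow = length(.K_PERFA), ncol = 3,
              dimnames = list(.K_PERFA, fatty_acids()))
  if (!is.null(perfa)) {
    perfa <- as.matrix(perfa)
    if (is.null(rownames(perfa)) || is.null(colnames(perfa)))
      stop("`perfa` must have constant rownames and fatty-acid colnames")
    bad <- setdiff(rownames(perfa), .K_PERFA)
    if (length(bad))
      stop("unknown per-fatty-acid constant(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(colnames(perfa), fatty_acids())
    if (length(bad))
      stop("unknown fatty-acid label(s): ", paste(bad, collapse = ", "))
    m[rownames(perfa), colnames(perfa)] <- perfa
  }
  s <- setNames(numeric(length(.K_SHARED)), .K_SHARED)
  if (!is.null(shared)) {
    bad <- setdiff(names(shared), .K_SHARED)
    if (length(bad))
      stop("unknown shared constant(s): ", paste(bad, collapse = ", "))
    s[names(shared)] <- shared
  }
  if (any(m < 0, na.rm = TRUE) || any(s < 0))
    stop("rate constants must be non-negative")
  if (enforce_fe_ratio) m["kpro1", ] <- m["kpro2", ] / 100
  structure(list(perfa = m, shared = s,
                 enforce_fe_ratio = enforce_fe_ratio),
            class = "ox_constants")
}

#' @export
print.ox_constants <- function(x, ...) {
  cat("Kinetic rate constants (kg mmol^-1 s^-1; kd in 1/s)\n")
  print(signif(x$perfa, 3))
  cat("shared antioxidant constants:\n")
  print(signif(x$shared, 3))
  invisible(x)
}

#' Read or modify a single constant
#'
#' @param k An `ox_constants` object.
#' @param constant Constant name (per-fatty-acid or shared).
#' @param fatty_acid Fatty-acid label for per-fatty-acid constants;
#'   ignored for shared constants.
#' @return `get_constant()` returns the numeric value; `set_constant()`
#'   returns the modified `ox_constants` object (the `kpro1 = kpro2/100`
#'   tie is re-applied when active).
#' @export
get_constant <- function(k, constant, fatty_acid = NULL) {
  stopifnot(inherits(k, "ox_constants"))
  if (constant %in% .K_SHARED) return(unname(k$shared[constant]))
  if (!constant %in% .K_PERFA) stop("unknown constant: ", constant)
  if (is.null(fatty_acid))
    stop("per-fatty-acid constant '", constant, "' needs `fatty_acid`")
  k$perfa[constant, fatty_acid]
}

#' @rdname get_constant
#' @param value New non-negative value.
#' @export
set_constant <- function(k, constant, value, fatty_acid = NULL) {
  stopifnot(inherits(k, "ox_constants"), value >= 0)
  if (constant %in% .K_SHARED) {
    k$shared[constant] <- value
  } else if (constant %in% .K_PERFA) {
    if (is.null(fatty_acid))
      stop("per-fatty-acid constant '", constant, "' needs `fatty_acid`")
    k$perfa[constant, fatty_acid] <- value
    if (isTRUE(k$enforce_fe_ratio)) k$perfa["kpro1", ] <- k$perfa["kpro2", ] / 100
  } else stop("unknown constant: ", constant)
  k
}

#' Scale selected constants by an acceleration factor
#'
#' Implements the critical-hydroperoxide acceleration `k -> f * k` applied
#' once the total LOOH concentration crosses the critical threshold.
#'
#' @param k An `ox_constants` object.
#' @param f Either a single factor applied to `constants`, or a named
#'   vector of per-constant factors (names are constant names).
#' @param constants Constants the single factor applies to; the default is
#'   the LOOH-consuming and propagation set.
#' @return The scaled `ox_constants`.
#' @export
apply_acceleration <- function(k, f,
                               constants = c("kd", "kpro1", "kpro2", "kbimol",
                                             "kloh2", "ke4", "kp2", "kp1")) {
  stopifnot(inherits(k, "ox_constants"))
  fmap <- if (length(f) == 1L && is.null(names(f)))
    setNames(rep(f, length(constants)), constants) else f
  if (is.null(names(fmap))) stop("`f` must be a scalar or a named vector")
  for (nm in names(fmap)) {
    if (nm %in% .K_PERFA) k$perfa[nm, ] <- k$perfa[nm, ] * fmap[[nm]]
    else if (nm %in% .K_SHARED) k$shared[nm] <- k$shared[nm] * fmap[[nm]]
    else stop("unknown constant in acceleration map: ", nm)
  }
  if (isTRUE(k$enforce_fe_ratio)) k$perfa["kpro1", ] <- k$perfa["kpro2", ] / 100
  k
}

#' NMR-acquisition correction for highly reactive substrates
#'
#' During NMR acquisition of trilinolenin samples, oxidation continues in
#' the spectrometer; the apparent extra formation of aldehydes and
#' hydroxides is modelled as proportional to the LOOH formation rate,
#' adding `alpha * d[LOOH]/dt` to the ALD and LOH balances.
#'
#' @param alpha_ALD,alpha_LOH Dimensionless proportionality constants.
#' @param enabled Whether the correction terms are active (trilinolenin
#'   substrate only).
#' @return An object of class `ox_alpha`.
#' @export
alpha_correction <- function(alpha_ALD = 0.0018, alpha_LOH = 0.0025,
                             enabled = FALSE) {
  stopifnot(alpha_ALD >= 0, alpha_LOH >= 0)
  structure(list(alpha_ALD = alpha_ALD, alpha_LOH = alpha_LOH,
                 enabled = isTRUE(enabled)),
            class = "ox_alpha")
}
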