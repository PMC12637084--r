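# Synthetic-data generator emulating NMR-quantified oxidation time courses:
# preset experimental designs (model TAGs and two oil blends), measurement
# noise at platform-realistic relative standard deviations, and
# detection/quantification-limit censoring.

.LOD_LOOH_ALD <- 0.03  # mmol/kg, 1D NMR classes (LOOH, ALD)
.LOQ_OTHER <- 0.6      # mmol/kg, 2D NMR classes (KET, LOH, EP, EPOOH)

#' Define a synthetic experiment design
#'
#' @param name Design label (used as substrate id).
#' @param composition Named mole fractions (see [sim_config()]).
#' @param temps_C Incubation temperatures (degrees Celsius).
#' @param horizons_days Sampling horizon per temperature (recycled);
#'   hotter incubations finish sooner, so horizons shrink with
#'   temperature.
#' @param n_samples Number of sampling times after t0, evenly spaced over
#'   each horizon.
#' @param vial An `ox_vial` preset.
#' @param rsd Relative standard deviation of the measurement noise,
#'   either a scalar or named per product class; platform values range
#'   from 1 to 10 percent.
#' @param AH0,LOOH0,Fe2_0,Fe3_0 Initial concentrations (mmol/kg).
#' @param alpha An [alpha_correction()] (enabled for trilinolenin).
#' @param lod,loq Censoring limits (mmol/kg) for the LOOH/ALD and
#'   remaining classes respectively.
#' @return An object of class `ox_design`.
#' @export
design_spec <- function(name, composition, temps_C, horizons_days,
                        n_samples = 16, vial, rsd = 0.05, AH0 = 0,
                        LOOH0 = 1, Fe2_0 = 0, Fe3_0 = 0,
                        alpha = alpha_correction(),
                        lod = .LOD_LOOH_ALD, loq = .LOQ_OTHER) {
  stopifnot(length(temps_C) >= 1, all(horizons_days > 0))
  rsd_vec <- if (length(rsd) == 1L && is.null(names(rsd)))
    setNames(rep(rsd, 6), product_classes()) else rsd
  if (any(rsd_vec < 0 | rsd_vec > 0.2))
    stop("per-class RSD outside the plausible 0-20 % window")
  structure(list(name = name, composition = composition, temps_C = temps_C,
                 horizons_days = rep_len(horizons_days, length(temps_C)),
                 n_samples = n_samples, vial = vial, rsd = rsd_vec,
                 AH0 = AH0, LOOH0 = LOOH0, Fe2_0 = Fe2_0, Fe3_0 = Fe3_0,
                 alpha = alpha, lod = lod, loq = loq),
            class = "ox_design")
}

# model-TAG vial: 3.75 mL, 14 mm id, 50 mg oil, air-tight stopper
.vial_tag <- function() {
  vial_from_geometry(3.75e-6, 14e-3, 50e-6 / 915, oil_density = 915)
}

#' Shipped experiment-design presets
#'
#' Five designs emulating the study conditions: the three pure model
#' triacylglycerols at four evenly spaced temperatures over their
#' respective incubation ranges (40-70, 25-60 and 4-40 degrees C; the
#' more unsaturated the substrate, the colder the range), a
#' rapeseed-like blend with endogenous tocopherol, and a stripped
#' sunflower-like blend. Sampling horizons were fixed per temperature so
#' each curve develops to its oxygen-limited plateau.
#'
#' @param name One of `"triolein"`, `"trilinolein"`, `"trilinolenin"`,
#'   `"rapeseed"`, `"sunflower"`; `NULL` returns the full named list.
#' @param rsd,n_samples Overrides applied to the preset.
#' @return An `ox_design`, or a named list of all designs.
#' @export
preset_design <- function(name = NULL, rsd = 0.05, n_samples = 16) {
  designs <- list(
    triolein = design_spec(
      "triolein", c("18:1" = 1), temps_C = c(40, 50, 60, 70),
      horizons_days = c(160, 130, 90, 50), n_samples = n_samples,
      vial = .vial_tag(), rsd = rsd,
      Fe2_0 = 1.43e-3, Fe3_0 = 1.43e-3),
    trilinolein = design_spec(
      "trilinolein", c("18:2" = 1), temps_C = c(25, 36.67, 48.33, 60),
      horizons_days = c(120, 56, 24, 10), n_samples = n_samples,
      vial = .vial_tag(), rsd = rsd),
    trilinolenin = design_spec(
      "trilinolenin", c("18:3" = 1), temps_C = c(4, 16, 28, 40),
      horizons_days = c(60, 32, 16, 8), n_samples = n_samples,
      vial = .vial_tag(), rsd = rsd,
      alpha = alpha_correction(enabled = TRUE)),
    rapeseed = design_spec(
      "rapeseed",
      c("18:1" = 0.62, "18:2" = 0.19, "18:3" = 0.08, saturated = 0.11),
      temps_C = c(20, 40, 60), horizons_days = c(720, 240, 21),
      n_samples = n_samples,
      vial = vial_from_geometry(20.4e-6, 20.5e-3, 1e-6, oil_density = 920,
                                P_cap = 1e-11),
      rsd = rsd, AH0 = 1, LOOH0 = 4),
    sunflower = design_spec(
      "sunflower", c("18:1" = 0.31, "18:2" = 0.59, saturated = 0.10),
      temps_C = 25, horizons_days = 200, n_samples = n_samples,
      vial = vial_from_geometry(25e-6, 20.6e-3, 1e-6, oil_density = 920,
                                P_cap = 1e-11),
      rsd = rsd, LOOH0 = 4))
  if (is.null(name)) return(designs)
  if (!name %in% names(designs))
    stop("unknown design preset: ", name)
  designs[[name]]
}

#' @rdname preset_design
#' @export
preset_designs <- function() preset_design(NULL)

# simulation config of one (design, temperature) cell
.design_config <- function(design, i, t_days = NULL) {
  if (is.null(t_days))
    t_days <- seq(0, design$horizons_days[i],
                  length.out = design$n_samples + 1)
  sim_config(composition = design$composition,
             temperature_C = design$temps_C[i], t_days = t_days,
             vial = design$vial, LOOH0 = design$LOOH0, AH0 = design$AH0,
             Fe2_0 = design$Fe2_0, Fe3_0 = design$Fe3_0,
             alpha = design$alpha)
}

#' Generate a synthetic NMR-style dataset
#'
#' Simulates the ground truth for every temperature of the design,
#' samples the product-class totals at the design's schedule, applies
#' multiplicative Gaussian measurement noise (per-class relative
#' standard deviation, deviates via [box_muller()]), flags values below
#' the detection limit (LOOH/ALD) or quantification limit (other
#' classes) as censored, and returns the series together with the
#' generating truth for recovery scoring. Fully reproducible from the
#' seed.
#'
#' @param design An `ox_design`.
#' @param truth Either an `ox_ea_table` (interpolated per temperature,
#'   shared constants attached from the shipped set) or a function
#'   `function(temp_C) -> ox_constants`.
#' @param seed Mandatory RNG seed.
#' @return An [ox_dataset()] whose `truth` field records the generating
#'   constants per temperature and whose `data` follows the series CSV
#'   schema.
#' @export
generate_dataset <- function(design, truth = default_ea_table(), seed) {
  stopifnot(inherits(design, "ox_design"))
  if (missing(seed)) stop("a seed is mandatory for dataset generation")
  k_of <- if (inherits(truth, "ox_ea_table")) {
    function(temp_C) constants_at_temperature(
      truth, temp_C, shared = default_shared_constants())
  } else if (is.function(truth)) truth else
    stop("truth must be an ox_ea_table or a function(temp_C)")
  set.seed(seed)
  rows <- list()
  configs <- list()
  k_by_temp <- list()
  for (i in seq_along(design$temps_C)) {
    temp <- design$temps_C[i]
    cfg <- .design_config(design, i)
    k <- k_of(temp)
    traj <- simulate_oxidation(cfg, k)
    ct <- class_totals(traj)
    for (cls in product_classes()) {
      truth_vals <- ct[[cls]]
      rsd <- design$rsd[[cls]]
      noisy <- truth_vals * (1 + rsd * box_muller(length(truth_vals)))
      noisy <- pmax(noisy, 0)
      limit <- if (cls %in% c("LOOH", "ALD")) design$lod else design$loq
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = design$name, temperature_C = temp, product_class = cls,
        fatty_acid = NA_character_, time_days = ct$time_days,
        conc_mmol_per_kg = noisy, sd = rsd * truth_vals,
        censored = noisy < limit)
    }
    configs[[as.character(temp)]] <- cfg
    k_by_temp[[as.character(temp)]] <- k
  }
  data <- do.call(rbind, rows)
  ox_dataset(data, configs,
             truth = list(table = if (inherits(truth, "ox_ea_table")) truth,
                          constants = k_by_temp, seed = seed),
             design = design)
}
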