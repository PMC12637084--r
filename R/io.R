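# Tabular readers/writers (experiment series, constant and Arrhenius
# tables), YAML run configuration, and the pure forward-prediction
# entry point used by the command-line script.

.SERIES_COLS <- c("substrate", "temperature_C", "product_class",
                  "fatty_acid", "time_days", "conc_mmol_per_kg", "sd",
                  "censored")

#' Read an experiment series CSV
#'
#' Schema: `substrate, temperature_C, product_class, fatty_acid,
#' time_days, conc_mmol_per_kg, sd, censored`; `fatty_acid`, `sd` and
#' `censored` are optional. A missing `sd` column is filled from the
#' relative-standard-deviation model `sd = rsd * concentration`.
#'
#' @param path CSV path.
#' @param rsd Relative standard deviation used when the file carries no
#'   `sd` column.
#' @return A data.frame in the series schema.
#' @export
read_series <- function(path, rsd = 0.05) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0) stop("empty series file: ", path)
  need <- c("substrate", "temperature_C", "product_class", "time_days",
            "conc_mmol_per_kg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("series file misses column(s): ", paste(miss, collapse = ", "))
  for (col in c("temperature_C", "time_days", "conc_mmol_per_kg")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop(sprintf("malformed value in column '%s', line %d", col,
                   which(is.na(v) & !is.na(df[[col]]))[1] + 1L))
    df[[col]] <- v
  }
  if (is.null(df$fatty_acid)) df$fatty_acid <- NA_character_
  if (is.null(df$sd)) df$sd <- rsd * df$conc_mmol_per_kg
  if (is.null(df$censored)) df$censored <- FALSE
  df$censored <- as.logical(df$censored)
  df[, .SERIES_COLS]
}

#' Write an experiment series CSV
#'
#' @param series Data frame in the series schema.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_series <- function(series, path) {
  write.csv(series[, intersect(.SERIES_COLS, names(series))], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an Arrhenius parameter table (TSV)
#'
#' Columns `constant, fatty_acid, Ea_kJ_per_mol, k_ref, T_ref_C`; the
#' string `"nd"` (or an empty field) marks entries without an activation
#' energy.
#'
#' @param path TSV path.
#' @return `read_ea_table()` returns an `ox_ea_table`.
#' @export
read_ea_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ea <- suppressWarnings(as.numeric(ifelse(df$Ea_kJ_per_mol %in%
                                             c("nd", "n.d.", ""),
                                           NA, df$Ea_kJ_per_mol)))
  arrhenius_table(df$constant, df$fatty_acid, ea, as.numeric(df$k_ref),
                  as.numeric(df$T_ref_C))
}

#' @rdname read_ea_table
#' @param tab An `ox_ea_table`.
#' @export
write_ea_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$Ea_kJ_per_mol <- ifelse(is.na(out$Ea_kJ_per_mol), "nd",
                              format(out$Ea_kJ_per_mol))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a flat rate-constant table (TSV)
#'
#' Columns `constant, fatty_acid, value`; shared antioxidant constants
#' use `fatty_acid = "shared"`.
#'
#' @param path TSV path.
#' @return `read_constants()` returns an `ox_constants`.
#' @export
read_constants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  shared <- df[df$fatty_acid == "shared", ]
  perfa <- df[df$fatty_acid != "shared", ]
  m <- matrix(0, length(.K_PERFA), 3,
              dimnames = list(.K_PERFA, fatty_acids()))
  m[cbind(perfa$constant, perfa$fatty_acid)] <- as.numeric(perfa$value)
  rate_constant_set(m, setNames(as.numeric(shared$value), shared$constant),
                    enforce_fe_ratio = FALSE)
}

#' @rdname read_constants
#' @param k An `ox_constants`.
#' @export
write_constants <- function(k, path) {
  stopifnot(inherits(k, "ox_constants"))
  df <- rbind(
    data.frame(constant = rep(rownames(k$perfa), 3),
               fatty_acid = rep(colnames(k$perfa), each = nrow(k$perfa)),
               value = as.vector(k$perfa)),
    data.frame(constant = names(k$shared), fatty_acid = "shared",
               value = unname(k$shared)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.RUN_COMMANDS <- c("simulate", "fit", "mc", "sa", "arrhenius", "interpolate",
                   "fit-ah", "fit-accel", "synth", "predict")
.STOCHASTIC_COMMANDS <- c("mc", "synth", "fit")

#' Load and validate a YAML run configuration
#'
#' Applies defaults (solver tolerances, verbosity) and enforces that
#' stochastic commands carry an explicit seed.
#'
#' @param path YAML file with at least a `command` field.
#' @return A validated list of class `ox_runconfig`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$command)) stop("config schema violation: missing 'command'")
  if (!cfg$command %in% .RUN_COMMANDS)
    stop("config schema violation: unknown command '", cfg$command, "'")
  defaults <- list(out_dir = ".", verbosity = 1L, rtol = 1e-7, atol = 1e-10,
                   seed = NULL)
  cfg <- modifyList(defaults, cfg)
  if (cfg$command %in% .STOCHASTIC_COMMANDS && is.null(cfg$seed))
    stop("config schema violation: command '", cfg$command,
         "' requires an explicit 'seed'")
  class(cfg) <- "ox_runconfig"
  cfg
}

#' Save a run configuration back to YAML
#'
#' @param cfg An `ox_runconfig` (or plain list).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Forward prediction of oil oxidation from composition alone
#'
#' Pure prediction: interpolates the Arrhenius table to the storage
#' temperature (with the mixing rules engaged through the network RHS)
#' and simulates the storage horizon. No data-dependent tuning happens
#' here; when reference data are supplied they are only scored (NRMSE
#' per class).
#'
#' @param composition Named mole fractions (see [sim_config()]).
#' @param temperature_C Storage temperature.
#' @param days Horizon (days); the grid is 200 evenly spaced points.
#' @param vial An `ox_vial`.
#' @param ea_table Arrhenius table (default: shipped fixture).
#' @param AH0 Initial tocopherol concentration (mmol/kg).
#' @param reference Optional series data.frame to score against.
#' @param ... Passed to [sim_config()].
#' @return A list with the `trajectory`, a `summary` data.frame of
#'   time-to-threshold milestones, and `nrmse` per class when reference
#'   data were given.
#' @export
predict_oxidation <- function(composition, temperature_C, days, vial,
                              ea_table = default_ea_table(), AH0 = 0,
                              reference = NULL, ...) {
  k <- constants_at_temperature(ea_table, temperature_C,
                                shared = default_shared_constants())
  cfg <- sim_config(composition = composition, temperature_C = temperature_C,
                    t_days = seq(0, days, length.out = 201), vial = vial,
                    AH0 = AH0, ...)
  traj <- simulate_oxidation(cfg, k)
  ct <- class_totals(traj)
  summary <- data.frame(
    milestone = c("LOOH_10", "LOOH_50", "LOOH_100"),
    time_days = c(time_to_threshold(traj, 10), time_to_threshold(traj, 50),
                  time_to_threshold(traj, 100)))
  out <- list(trajectory = traj, summary = summary)
  if (!is.null(reference)) {
    sc <- vapply(intersect(unique(reference$product_class),
                           product_classes()), function(cls) {
      sub <- reference[reference$product_class == cls & !reference$censored, ]
      mod <- approx(ct$time_days, ct[[cls]], xout = sub$time_days,
                    rule = 2)$y
      nrmse(mod, sub$conc_mmol_per_kg)
    }, numeric(1))
    out$nrmse <- sc
  }
  out
}
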