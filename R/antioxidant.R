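# Antioxidant-efficacy estimation from early hydroperoxide formation, and
# the critical-hydroperoxide acceleration fit for late-stage storage.

#' Fit the antioxidant constants from early LOOH data
#'
#' Tocopherol efficacy is identifiable from the induction period alone:
#' only LOOH data from the early window (total LOOH at or below
#' `looh_ceiling`, at least `min_points` points) enter the objective, and
#' only the five shared antioxidant constants (`kAH1`, `kAH2`, `kAH3`,
#' `kt4`, `kt5`) are adjusted — every lipid constant stays frozen at its
#' supplied value. By default the weakly identifiable `kAH2`/`kAH3` are
#' boxed within two decades of their starts.
#'
#' @param dataset An `ox_dataset` whose configs carry a nonzero initial
#'   antioxidant concentration.
#' @param k_fixed `ox_constants` with the frozen lipid constants and the
#'   antioxidant starting values.
#' @param looh_ceiling Early-window LOOH ceiling (mmol/kg).
#' @param min_points Minimum number of usable early points.
#' @param spec Adjustable constants (default: the five shared ones).
#' @param bounds_decades Box half-width around the starts.
#' @param n_starts,seed,maxit Passed to [fit_kinetics()].
#' @return An `ox_ahfit`: the fitted shared constants, the underlying
#'   `ox_fit`, the window actually used, and an `unidentifiable` flag
#'   (set when the data do not respond to the antioxidant constants,
#'   e.g. with no antioxidant present).
#' @export
fit_antioxidant <- function(dataset, k_fixed, looh_ceiling = 10,
                            min_points = 3,
                            spec = fit_spec(c("kAH1", "kAH2", "kAH3",
                                              "kt4", "kt5")),
                            bounds_decades = 2, n_starts = 1, seed = 1,
                            maxit = 50) {
  stopifnot(inherits(dataset, "ox_dataset"))
  d <- dataset$data
  keep <- d$product_class == "LOOH" & !d$censored &
    d$conc_mmol_per_kg <= looh_ceiling
  if (sum(keep) < min_points)
    stop(sprintf("insufficient data: %d early LOOH point(s) below %.3g mmol/kg (need >= %d)",
                 sum(keep), looh_ceiling, min_points))
  early <- dataset
  early$data <- d[keep, ]
  # normalisation range over the early window itself
  early <- ox_dataset(early$data, early$configs, truth = dataset$truth,
                      design = dataset$design)

  # identifiability probe: does the early objective react to kAH1 at all?
  sse0 <- objective_sse(k_fixed, early)
  sse1 <- objective_sse(set_constant(k_fixed, "kAH1",
                                     max(get_constant(k_fixed, "kAH1"), 1e-6) * 10),
                        early)
  unident <- isTRUE(all.equal(sse0, sse1, tolerance = 1e-10))
  if (unident) {
    warning("antioxidant constants are unidentifiable from these data ",
            "(objective does not respond); returning starting values")
    fit <- NULL
    k_hat <- k_fixed
  } else {
    fit <- fit_kinetics(early, k_fixed, spec = spec,
                        bounds_decades = bounds_decades,
                        n_starts = n_starts, seed = seed, maxit = maxit)
    k_hat <- fit$k
  }
  structure(list(constants = k_hat$shared, k = k_hat, fit = fit,
                 window = list(looh_ceiling = looh_ceiling,
                               n_points = sum(keep)),
                 unidentifiable = unident),
            class = "ox_ahfit")
}

#' @export
print.ox_ahfit <- function(x, ...) {
  cat("Antioxidant fit",
      if (x$unidentifiable) "(UNIDENTIFIABLE - starting values)" else "",
      "\n")
  print(signif(x$constants, 3))
  cat(sprintf("window: LOOH <= %.3g mmol/kg, %d points\n",
              x$window$looh_ceiling, x$window$n_points))
  invisible(x)
}

#' Predict the antioxidant decay curve
#'
#' Simulates the full network (antioxidant reactions included) and
#' returns the tocopherol trajectory; a consumption-only species, so the
#' curve is non-increasing.
#'
#' @param k `ox_constants` (typically from [fit_antioxidant()]).
#' @param config An `ox_config` with the storage conditions and `AH0`.
#' @return Data frame with `time_days` and `AH` (mmol/kg).
#' @export
predict_ah_decay <- function(k, config) {
  ct <- class_totals(simulate_oxidation(config, k))
  data.frame(time_days = ct$time_days, AH = ct$AH)
}

#' Fit the critical-hydroperoxide acceleration
#'
#' Jointly estimates the critical total LOOH concentration and the
#' shared acceleration factor `f` (applied to the LOOH-consuming and
#' propagation constants once the threshold is crossed) by least squares
#' against late-stage data, using the event-switched simulator. Start
#' values for the critical concentration default to the 80-95 mmol/kg
#' range reported for vegetable oils.
#'
#' @param dataset An `ox_dataset` spanning the acceleration onset
#'   (typically a single low-temperature series).
#' @param k_base Frozen base constants.
#' @param C_starts Starting values for the critical concentration
#'   (mmol/kg).
#' @param f_start Starting acceleration factor.
#' @param classes Product classes entering the objective.
#' @param C_bounds,f_bounds Box constraints (f on log10 scale
#'   internally; accelerations only, so f >= 1).
#' @param maxit Levenberg-Marquardt iteration cap per start.
#' @return An `ox_accelfit` with `C_crit`, `f`, the per-start table, the
#'   no-acceleration baseline SSE and an `identifiable` flag. When the
#'   baseline trajectory never reaches the smallest starting threshold,
#'   the fit reports no identifiable acceleration instead of estimates.
#' @export
fit_acceleration <- function(dataset, k_base, C_starts = c(80, 95),
                             f_start = 2, classes = "LOOH",
                             C_bounds = c(20, 300), f_bounds = c(1, 100),
                             maxit = 50) {
  stopifnot(inherits(dataset, "ox_dataset"), inherits(k_base, "ox_constants"))
  with_accel <- function(C_crit, f) {
    ds <- dataset
    ds$configs <- lapply(ds$configs, function(cfg) {
      cfg$accel <- accel_policy(enabled = TRUE, C_crit = C_crit, f = f)
      cfg
    })
    ds
  }
  base_sse <- objective_sse(k_base, dataset, classes = classes)
  # does the baseline ever reach the candidate thresholds?
  peak <- max(vapply(dataset$configs, function(cfg) {
    cfg$t_days <- sort(unique(c(0, dataset$data$time_days)))
    max(class_totals(simulate_oxidation(cfg, k_base))$LOOH)
  }, numeric(1)))
  obs_peak <- max(dataset$data$conc_mmol_per_kg[
    dataset$data$product_class == "LOOH" & !dataset$data$censored])
  if (max(peak, obs_peak) < min(C_starts))
    return(structure(list(identifiable = FALSE, C_crit = NA_real_,
                          f = NA_real_, sse = base_sse, base_sse = base_sse,
                          message = "no acceleration identifiable: LOOH never reaches the candidate thresholds",
                          per_start = NULL),
                     class = "ox_accelfit"))
  resfun <- function(par) {
    C_crit <- par[1]; f <- 10^par[2]
    r <- tryCatch(.residuals(k_base, with_accel(C_crit, f),
                             classes = classes),
                  error = function(e) NULL)
    if (is.null(r) || !length(r)) return(rep(1e3, 10))
    r
  }
  runs <- lapply(seq_along(C_starts), function(i) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = c(C_starts[i], log10(f_start)), fn = resfun,
                         lower = c(C_bounds[1], log10(f_bounds[1])),
                         upper = c(C_bounds[2], log10(f_bounds[2])),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-10, ptol = 1e-10,
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(ans)) return(c(NA, NA, Inf))
    c(ans$par[1], 10^ans$par[2], ans$deviance)
  })
  tab <- do.call(rbind, runs)
  colnames(tab) <- c("C_crit", "f", "sse")
  tab <- data.frame(start = C_starts, tab)
  best <- tab[which.min(tab$sse), ]
  identifiable <- is.finite(best$sse) && best$f > 1.05 &&
    best$sse < 0.99 * base_sse
  structure(list(identifiable = identifiable,
                 C_crit = if (identifiable) best$C_crit else NA_real_,
                 f = if (identifiable) best$f else NA_real_,
                 sse = best$sse, base_sse = base_sse,
                 message = if (identifiable) "ok" else
                   "no acceleration identifiable: f*k does not improve on the base model",
                 per_start = tab),
            class = "ox_accelfit")
}

#' @export
print.ox_accelfit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Acceleration fit:", x$message, "\n")
  } else {
    cat(sprintf("Acceleration fit: C_crit = %.1f mmol/kg, f = %.2f (SSE %.4g vs base %.4g)\n",
                x$C_crit, x$f, x$sse, x$base_sse))
  }
  invisible(x)
}
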