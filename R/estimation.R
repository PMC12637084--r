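# Multi-response estimation of kinetic constants from product-class time
# courses: range normalisation, the pooled sum-of-squares objective,
# bound-constrained Levenberg-Marquardt multistart fitting, Box-Muller
# Monte-Carlo uncertainty and local sensitivity analysis.

#' Range-normalise a curve against an experimental reference
#'
#' Both experimental and model curves are scaled by the experimental
#' curve's minimum and maximum, so concentrations of very different
#' magnitude (hydroperoxides vs ketones) weigh equally in the objective.
#' The experimental curve maps exactly onto [0, 1]; a model curve may
#' exceed that interval.
#'
#' @param x Curve to normalise.
#' @param ref Experimental reference curve (>= 2 distinct values).
#' @return Normalised curve.
#' @export
normalize_curve <- function(x, ref) {
  rng <- range(ref, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("degenerate range: reference curve is constant")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Normalised root mean square error
#'
#' RMSE of the residuals divided by the experimental range — the model's
#' goodness-of-fit score, commensurate with the range normalisation of
#' the objective. Values below 0.05 are conventionally read as a good
#' fit.
#'
#' @param model,expt Equal-length curves; the range is taken from `expt`.
#' @return Dimensionless NRMSE.
#' @export
nrmse <- function(model, expt) {
  if (length(model) != length(expt)) stop("curves must have equal length")
  rng <- diff(range(expt, na.rm = TRUE))
  if (rng <= 0) stop("degenerate range: experimental curve is constant")
  sqrt(mean((model - expt)^2)) / rng
}

#' Bundle experiment series with their simulation configs
#'
#' @param data Series data.frame (see [read_series()] for the schema).
#' @param configs Named list of `ox_config` objects, keyed by
#'   `as.character(temperature_C)`.
#' @param truth Optional generating-truth record (synthetic data).
#' @param design Optional design record.
#' @return An object of class `ox_dataset`. Per-class normalisation
#'   ranges are pooled over all temperatures of the dataset, using
#'   non-censored points.
#' @export
ox_dataset <- function(data, configs, truth = NULL, design = NULL) {
  stopifnot(all(c("temperature_C", "product_class", "time_days",
                  "conc_mmol_per_kg") %in% names(data)))
  if (is.null(data$censored)) data$censored <- FALSE
  if (is.null(data$sd)) data$sd <- 0
  miss <- setdiff(as.character(unique(data$temperature_C)), names(configs))
  if (length(miss))
    stop("no config for temperature(s): ", paste(miss, collapse = ", "))
  ok <- !data$censored
  rng <- do.call(rbind, lapply(split(data[ok, ], data$product_class[ok]),
                               function(d) data.frame(
                                 product_class = d$product_class[1],
                                 min = min(d$conc_mmol_per_kg),
                                 max = max(d$conc_mmol_per_kg))))
  rownames(rng) <- rng$product_class
  structure(list(data = data, configs = configs, class_range = rng,
                 truth = truth, design = design), class = "ox_dataset")
}

#' @export
print.ox_dataset <- function(x, ...) {
  cat(sprintf("Oxidation dataset: %d points, %d classes, temperatures %s degC\n",
              nrow(x$data), length(unique(x$data$product_class)),
              paste(sort(unique(x$data$temperature_C)), collapse = "/")))
  invisible(x)
}

# normalised residual vector of candidate constants against the dataset
.residuals <- function(k, dataset, temps = NULL, classes = NULL,
                       compiled = TRUE) {
  data <- dataset$data
  if (is.null(temps)) temps <- sort(unique(data$temperature_C))
  if (is.null(classes)) classes <- intersect(product_classes(),
                                             unique(data$product_class))
  res <- numeric(0)
  for (temp in temps) {
    cfg <- dataset$configs[[as.character(temp)]]
    sub <- data[data$temperature_C == temp &
                  data$product_class %in% classes & !data$censored, ]
    if (nrow(sub) == 0) next
    tt <- sort(unique(c(0, sub$time_days)))
    cfg$t_days <- tt
    traj <- simulate_oxidation(cfg, k, compiled = compiled)
    ct <- class_totals(traj)
    for (cls in classes) {
      dsub <- sub[sub$product_class == cls, ]
      if (nrow(dsub) == 0) next
      rng <- dataset$class_range[cls, ]
      if (is.na(rng$min) || rng$max - rng$min <= 0) next
      mod <- ct[[cls]][match(dsub$time_days, ct$time_days)]
      res <- c(res, (mod - dsub$conc_mmol_per_kg) / (rng$max - rng$min))
    }
  }
  res
}

#' Multi-response sum-of-squares objective
#'
#' Simulates every requested temperature of the dataset under candidate
#' constants, normalises model and data per product class by the pooled
#' experimental range, and sums the squared residuals over time points,
#' classes and temperatures. Censored points (below the detection /
#' quantification limit) are excluded. A failed simulation returns
#' `penalty` so an optimiser can continue.
#'
#' @param k Candidate `ox_constants`.
#' @param dataset An `ox_dataset`.
#' @param temps Temperatures to include (default all).
#' @param classes Product classes to include (default all present).
#' @param penalty Value returned on simulation failure.
#' @return The scalar SSE.
#' @export
objective_sse <- function(k, dataset, temps = NULL, classes = NULL,
                          penalty = 1e6) {
  r <- tryCatch(.residuals(k, dataset, temps, classes),
                error = function(e) NULL)
  if (is.null(r)) return(penalty)
  sum(r^2)
}

#' Describe which constants a fit adjusts
#'
#' @param constants Constant names.
#' @param fatty_acid Fatty-acid label for per-fatty-acid constants
#'   (recycled); use `NA` for shared antioxidant constants.
#' @return A data.frame fit specification.
#' @export
fit_spec <- function(constants, fatty_acid = NA_character_) {
  data.frame(constant = constants,
             fatty_acid = rep_len(fatty_acid, length(constants)),
             stringsAsFactors = FALSE)
}

# default adjustable set for an antioxidant-free substrate: the constants
# the product curves actually inform (terminations and kp1/kpro are
# insensitive or fixed by assumption)
.DEFAULT_FIT_CONSTANTS <- c("ki", "kp2", "kd", "kbimol", "kald", "kket",
                            "kloh1", "kloh2", "ke1", "ke2", "ke3", "ke4")

.theta_get <- function(k, spec) {
  vapply(seq_len(nrow(spec)), function(i) {
    v <- if (is.na(spec$fatty_acid[i]))
      get_constant(k, spec$constant[i])
    else get_constant(k, spec$constant[i], spec$fatty_acid[i])
    log10(v)
  }, numeric(1))
}

.theta_set <- function(k, spec, theta) {
  for (i in seq_len(nrow(spec))) {
    k <- if (is.na(spec$fatty_acid[i]))
      set_constant(k, spec$constant[i], 10^theta[i])
    else set_constant(k, spec$constant[i], 10^theta[i], spec$fatty_acid[i])
  }
  k
}

#' Fit kinetic constants to a dataset
#'
#' Bound-constrained nonlinear least squares (Levenberg-Marquardt on
#' log10-scaled constants) from one or more start points; the reported
#' estimate is the least-SSE multistart winner. Start point 1 is
#' `k_start` itself; further starts scatter the adjusted constants
#' log-uniformly within `start_scatter` decades (seeded, reproducible).
#'
#' @param dataset An `ox_dataset`.
#' @param k_start Starting `ox_constants` (also provides all frozen
#'   constants).
#' @param spec A [fit_spec()] of adjustable constants; default is the
#'   sensitive lipid set for the fatty acid carrying the most substrate.
#' @param temps Temperatures to fit (default all in the dataset); the
#'   constants are shared across the fitted temperatures.
#' @param classes Product classes entering the objective (default all
#'   present in the data).
#' @param n_starts Number of start points.
#' @param start_scatter Half-width (decades) of the multistart scatter.
#' @param bounds_decades Box half-width (decades) around the start theta.
#' @param seed Seed for the start scatter.
#' @param maxit Maximum Levenberg-Marquardt iterations per start.
#' @return An `ox_fit`: best constants, SSE, per-class NRMSE against the
#'   (pooled) data, and per-start diagnostics.
#' @export
fit_kinetics <- function(dataset, k_start, spec = NULL, temps = NULL,
                         classes = NULL, n_starts = 1, start_scatter = 1,
                         bounds_decades = 4, seed = 1, maxit = 100) {
  stopifnot(inherits(dataset, "ox_dataset"), inherits(k_start, "ox_constants"))
  if (is.null(spec))
    spec <- fit_spec(.DEFAULT_FIT_CONSTANTS, .dominant_fa(dataset))
  theta0 <- .theta_get(k_start, spec)
  if (any(!is.finite(theta0)))
    stop("k_start has a zero value for an adjustable constant: ",
         paste(spec$constant[!is.finite(theta0)], collapse = ", "))
  # optimise the log10 offset from the start values: a uniform parameter
  # scale around zero, so the finite-difference Jacobian probes every
  # constant by the same relative amount (epsfcn 1e-6 -> ~0.2 % in k,
  # comfortably above the integrator's output noise)
  npar <- length(theta0)
  starts <- list(rep(0, npar))
  if (n_starts > 1) {
    set.seed(seed)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- runif(npar, -start_scatter, start_scatter)
  }
  resfun <- function(delta) {
    k <- .theta_set(k_start, spec, theta0 + delta)
    r <- tryCatch(.residuals(k, dataset, temps, classes),
                  error = function(e) NULL)
    if (is.null(r) || !length(r) || any(!is.finite(r)))
      return(rep(1e3, max(1L, .n_points(dataset, temps))))
    r
  }
  runs <- lapply(seq_along(starts), function(i) {
    ans <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = resfun,
                         lower = rep(-bounds_decades, npar),
                         upper = rep(bounds_decades, npar),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-10, ptol = 1e-10,
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(ans)) return(list(sse = Inf, theta = theta0 + starts[[i]],
                                  info = -1L, start = i))
    list(sse = ans$deviance, theta = theta0 + ans$par, info = ans$info,
         start = i)
  })
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  if (all(!is.finite(sses)))
    stop("estimation error: all starts failed (",
         paste(vapply(runs, `[[`, integer(1), "info"), collapse = ","), ")")
  best <- runs[[which.min(sses)]]
  k_hat <- .theta_set(k_start, spec, best$theta)
  structure(list(k = k_hat, theta = best$theta, spec = spec,
                 sse = best$sse, start_id = best$start,
                 nrmse = fit_nrmse(k_hat, dataset, temps),
                 temps = temps,
                 per_start = data.frame(
                   start = seq_along(runs),
                   sse = sses,
                   info = vapply(runs, `[[`, integer(1), "info"))),
            class = "ox_fit")
}

.dominant_fa <- function(dataset) {
  cf <- dataset$configs[[1]]
  comp <- cf$composition[intersect(names(cf$composition), fatty_acids())]
  names(comp)[which.max(comp)]
}

.n_points <- function(dataset, temps = NULL) {
  d <- dataset$data
  if (!is.null(temps)) d <- d[d$temperature_C %in% temps, ]
  sum(!d$censored)
}

#' @export
print.ox_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: SSE %.4g (start %d of %d), max class NRMSE %.3f\n",
              x$sse, x$start_id, nrow(x$per_start), max(x$nrmse)))
  est <- setNames(10^x$theta, paste0(x$spec$constant,
                                     ifelse(is.na(x$spec$fatty_acid), "",
                                            paste0("(", x$spec$fatty_acid, ")"))))
  print(signif(est, 3))
  invisible(x)
}

#' Per-class NRMSE of a constant set against a dataset
#'
#' Model curves are simulated per temperature and compared with the
#' non-censored data of each product class, pooled over the selected
#' temperatures; the normalising range is the pooled experimental range.
#'
#' @param k An `ox_constants`.
#' @param dataset An `ox_dataset`.
#' @param temps Temperatures to include (default all).
#' @return Named vector of NRMSE per product class.
#' @export
fit_nrmse <- function(k, dataset, temps = NULL) {
  data <- dataset$data
  if (is.null(temps)) temps <- sort(unique(data$temperature_C))
  classes <- intersect(product_classes(), unique(data$product_class))
  acc <- setNames(vector("list", length(classes)), classes)
  for (temp in temps) {
    cfg <- dataset$configs[[as.character(temp)]]
    sub <- data[data$temperature_C == temp & !data$censored, ]
    if (nrow(sub) == 0) next
    cfg$t_days <- sort(unique(c(0, sub$time_days)))
    ct <- class_totals(simulate_oxidation(cfg, k))
    for (cls in classes) {
      dsub <- sub[sub$product_class == cls, ]
      if (nrow(dsub) == 0) next
      mod <- ct[[cls]][match(dsub$time_days, ct$time_days)]
      acc[[cls]] <- rbind(acc[[cls]],
                          cbind(mod = mod, obs = dsub$conc_mmol_per_kg))
    }
  }
  vapply(classes, function(cls) {
    m <- acc[[cls]]
    if (is.null(m)) return(NA_real_)
    nrmse(m[, "mod"], m[, "obs"])
  }, numeric(1))
}

#' Staged fit of one temperature: chain constants first, then all
#'
#' The LOOH curve is governed by the radical-chain constants (`ki`,
#' `kp2`, `kd`, `kbimol`); fitting those against LOOH alone first, then
#' releasing the product-branch constants against all classes, and
#' finally polishing the full set jointly avoids the local minima that
#' trap a cold full-parameter fit. Each stage is a multistart
#' [fit_kinetics()] call.
#'
#' @param dataset An `ox_dataset`.
#' @param k_start Starting `ox_constants`.
#' @param temp Temperature to fit.
#' @param spec Full adjustable set (default as in [fit_kinetics()]);
#'   stage one uses its intersection with the chain constants.
#' @param n_starts Multistarts for the first two stages.
#' @param seed,maxit As in [fit_kinetics()].
#' @return The polished `ox_fit`.
#' @export
fit_staged <- function(dataset, k_start, temp, spec = NULL, n_starts = 3,
                       seed = 1, maxit = 200) {
  if (is.null(spec))
    spec <- fit_spec(.DEFAULT_FIT_CONSTANTS, .dominant_fa(dataset))
  chain <- spec[spec$constant %in% c("ki", "kp2", "kd", "kbimol"), ]
  k1 <- if (nrow(chain) && "LOOH" %in% dataset$data$product_class) {
    f1 <- fit_kinetics(dataset, k_start, spec = chain, temps = temp,
                       classes = "LOOH", n_starts = n_starts, seed = seed,
                       maxit = maxit)
    f1$k
  } else k_start
  f2 <- fit_kinetics(dataset, k1, spec = spec, temps = temp,
                     n_starts = n_starts, seed = seed + 1, maxit = maxit)
  # final polish from the multistart winner
  fit_kinetics(dataset, f2$k, spec = spec, temps = temp, n_starts = 1,
               maxit = 2 * maxit)
}

#' Fit every temperature of a dataset and pool the results
#'
#' Runs [fit_kinetics()] separately per incubation temperature (the
#' constants are temperature specific), then reports the per-temperature
#' estimates side by side, the per-class NRMSE pooled over all
#' temperatures, and — when two or more temperatures were fitted — the
#' activation energies estimated from the per-temperature constants.
#'
#' @param dataset An `ox_dataset`.
#' @param k_start_of Function `temp_C -> ox_constants` supplying the
#'   start values per temperature (default: the shipped coarse start
#'   table interpolated to each temperature).
#' @param spec A [fit_spec()]; default as in [fit_kinetics()].
#' @param method `"staged"` (default, see [fit_staged()]) or `"direct"`
#'   (one multistart [fit_kinetics()] call per temperature).
#' @param ... Passed to [fit_staged()] or [fit_kinetics()] (`n_starts`,
#'   `seed`, `maxit`, ...).
#' @return A list of class `ox_multifit`: `fits` (named by temperature),
#'   `k_by_temp` (matrix constants x temperatures), `nrmse` (pooled per
#'   class), `ea` (an `ox_ea_table` or `NULL`).
#' @export
fit_dataset <- function(dataset, k_start_of = default_start_constants,
                        spec = NULL, method = c("staged", "direct"), ...) {
  stopifnot(inherits(dataset, "ox_dataset"))
  method <- match.arg(method)
  temps <- sort(unique(dataset$data$temperature_C))
  if (is.null(spec))
    spec <- fit_spec(.DEFAULT_FIT_CONSTANTS, .dominant_fa(dataset))
  fits <- lapply(temps, function(tm) {
    if (method == "staged")
      fit_staged(dataset, k_start_of(tm), temp = tm, spec = spec, ...)
    else
      fit_kinetics(dataset, k_start_of(tm), spec = spec, temps = tm, ...)
  })
  names(fits) <- as.character(temps)
  k_by_temp <- vapply(fits, function(f) 10^f$theta, numeric(nrow(spec)))
  rownames(k_by_temp) <- spec$constant
  colnames(k_by_temp) <- as.character(temps)
  # pooled per-class NRMSE from the per-temperature winners
  classes <- intersect(product_classes(), unique(dataset$data$product_class))
  acc <- setNames(vector("list", length(classes)), classes)
  for (tm in temps) {
    cfg <- dataset$configs[[as.character(tm)]]
    sub <- dataset$data[dataset$data$temperature_C == tm &
                          !dataset$data$censored, ]
    cfg$t_days <- sort(unique(c(0, sub$time_days)))
    ct <- class_totals(simulate_oxidation(cfg, fits[[as.character(tm)]]$k))
    for (cls in classes) {
      dsub <- sub[sub$product_class == cls, ]
      if (nrow(dsub) == 0) next
      acc[[cls]] <- rbind(acc[[cls]],
                          cbind(mod = ct[[cls]][match(dsub$time_days,
                                                      ct$time_days)],
                                obs = dsub$conc_mmol_per_kg))
    }
  }
  pooled <- vapply(classes, function(cls)
    nrmse(acc[[cls]][, "mod"], acc[[cls]][, "obs"]), numeric(1))
  ea <- NULL
  if (length(temps) >= 2 && all(is.na(spec$fatty_acid) == FALSE))
    ea <- tryCatch(estimate_ea_table(k_by_temp, spec$fatty_acid[1]),
                   error = function(e) NULL)
  structure(list(fits = fits, k_by_temp = k_by_temp, nrmse = pooled,
                 ea = ea, spec = spec),
            class = "ox_multifit")
}

#' @export
print.ox_multifit <- function(x, ...) {
  cat(sprintf("Per-temperature kinetic fits (%s degC)\n",
              paste(colnames(x$k_by_temp), collapse = "/")))
  print(signif(x$k_by_temp, 3))
  cat("pooled class NRMSE:\n")
  print(round(x$nrmse, 4))
  invisible(x)
}

#' Gaussian deviates by the Box-Muller transform
#'
#' Standard construction: for uniform pairs (r1, r2),
#' `z = sqrt(-2 log r1) * cos(2 pi r2)` is standard normal. The
#' `"literal"` mode instead returns the plain product `r1 * r2` of the
#' two uniforms (an alternative, non-Gaussian noise multiplier kept for
#' comparison).
#'
#' @param n Number of deviates.
#' @param mode `"standard"` (Gaussian) or `"literal"`.
#' @return Numeric vector of length `n`. Uses R's RNG stream; seed with
#'   `set.seed()` for reproducibility.
#' @export
box_muller <- function(n, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  r1 <- runif(n)
  r2 <- runif(n)
  if (mode == "literal") return(r1 * r2)
  sqrt(-2 * log(r1)) * cos(2 * pi * r2)
}

#' Monte-Carlo parameter uncertainty
#'
#' Perturbs every non-censored datum with zero-mean Gaussian noise of its
#' stated standard deviation (deviates generated by the Box-Muller
#' transform), refits from the reference estimate, and aggregates the
#' spread of the re-estimated constants. With constants estimated at two
#' or more temperatures, activation energies are re-estimated per
#' replicate as well.
#'
#' @param dataset An `ox_dataset` (its `sd` column supplies sigma).
#' @param fits Either a single `ox_fit` (constants shared over all
#'   temperatures) or a named list of per-temperature `ox_fit`s.
#' @param n Number of Monte-Carlo iterations (200 in the reference
#'   protocol).
#' @param seed RNG seed.
#' @param maxit Iterations per warm-started refit.
#' @param noise_mode Passed to [box_muller()].
#' @return An `ox_mc` with per-constant (per-temperature) mean, sd and
#'   relative sd over replicates, Ea statistics when applicable, and
#'   failure diagnostics.
#' @export
monte_carlo <- function(dataset, fits, n = 200, seed = 1, maxit = 25,
                        noise_mode = "standard") {
  single <- inherits(fits, "ox_fit")
  if (single) fits <- list(fits)
  temps <- if (!is.null(names(fits)) && !single)
    as.numeric(names(fits)) else sort(unique(dataset$data$temperature_C))
  set.seed(seed)
  draws <- list()
  failed <- 0L
  for (i in seq_len(n)) {
    d <- dataset$data
    ok <- !d$censored
    d$conc_mmol_per_kg[ok] <- d$conc_mmol_per_kg[ok] +
      d$sd[ok] * box_muller(sum(ok), mode = noise_mode)
    pert <- dataset
    pert$data <- d
    rep_i <- tryCatch({
      lapply(seq_along(fits), function(j) {
        ft <- fits[[j]]
        tj <- if (single) NULL else temps[j]
        refit <- fit_kinetics(pert, ft$k, spec = ft$spec, temps = tj,
                              n_starts = 1, maxit = maxit)
        10^refit$theta
      })
    }, error = function(e) NULL)
    if (is.null(rep_i)) { failed <- failed + 1L; next }
    draws[[length(draws) + 1L]] <- rep_i
  }
  if (!length(draws)) stop("all Monte-Carlo replicates failed")
  spec <- fits[[1]]$spec
  cn <- spec$constant
  # per fit-slot matrices: replicate x constant
  mats <- lapply(seq_along(fits), function(j)
    do.call(rbind, lapply(draws, `[[`, j)))
  stats <- do.call(rbind, lapply(seq_along(fits), function(j) {
    m <- mats[[j]]
    data.frame(constant = cn,
               temperature_C = if (single) NA_real_ else temps[j],
               mean = colMeans(m), sd = apply(m, 2, sd),
               rsd = apply(m, 2, sd) / colMeans(m))
  }))
  ea <- NULL
  if (!single && length(fits) >= 2) {
    ea_draws <- do.call(rbind, lapply(seq_along(draws), function(i) {
      vapply(seq_along(cn), function(ci) {
        kk <- vapply(seq_along(fits), function(j) mats[[j]][i, ci],
                     numeric(1))
        estimate_ea(kk, temps)$Ea_kJ_per_mol
      }, numeric(1))
    }))
    colnames(ea_draws) <- cn
    ea <- data.frame(constant = cn, mean = colMeans(ea_draws),
                     sd = apply(ea_draws, 2, sd),
                     rsd_percent = 100 * apply(ea_draws, 2, sd) /
                       abs(colMeans(ea_draws)))
  }
  structure(list(stats = stats, ea = ea, n_iterations = n,
                 n_failed = failed, seed = seed),
            class = "ox_mc")
}

#' @export
print.ox_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo uncertainty: %d iterations (%d failed)\n",
              x$n_iterations, x$n_failed))
  print(transform(x$stats, mean = signif(mean, 3), sd = signif(sd, 2),
                  rsd = signif(rsd, 2)), row.names = FALSE)
  if (!is.null(x$ea)) {
    cat("activation-energy spread:\n")
    print(transform(x$ea, mean = signif(mean, 4), sd = signif(sd, 2),
                    rsd_percent = signif(rsd_percent, 2)), row.names = FALSE)
  }
  invisible(x)
}

#' Local sensitivity analysis
#'
#' Multiplies each constant in turn by factors on a log grid spanning
#' 1/1000 to 1000, re-simulates, and scores the NRMSE of the adjusted
#' model against the reference model per product class (normalised by
#' the reference curve's range). A constant is insensitive when the
#' maximum NRMSE over all factors and classes stays below the threshold.
#'
#' @param k_ref Reference `ox_constants`.
#' @param config An `ox_config` defining the simulated experiment.
#' @param constants Constants to probe; default is every per-fatty-acid
#'   constant of the dominant fatty acid plus, when antioxidant is
#'   present, the shared constants.
#' @param factors Multiplicative factor grid.
#' @param threshold NRMSE insensitivity threshold.
#' @return An `ox_sa`: per-constant max NRMSE and classification, with
#'   the full factor-by-class map as an attribute.
#' @export
sensitivity_analysis <- function(k_ref, config,
                                 constants = NULL,
                                 factors = 10^seq(-3, 3),
                                 threshold = 0.05) {
  stopifnot(inherits(k_ref, "ox_constants"), inherits(config, "ox_config"))
  fas <- names(config$composition)[names(config$composition) %in%
                                     fatty_acids()]
  fas <- fas[config$composition[fas] > 0]
  if (is.null(constants)) {
    constants <- .K_PERFA
    if (config$AH0 > 0) constants <- c(constants, .K_SHARED)
  }
  ref <- class_totals(simulate_oxidation(config, k_ref))
  classes <- product_classes()
  rngs <- vapply(classes, function(cls) diff(range(ref[[cls]])), numeric(1))
  map <- list()
  rows <- lapply(constants, function(cn) {
    worst <- 0
    failed <- FALSE
    for (f in factors) {
      if (f == 1) next
      k2 <- k_ref
      if (cn %in% .K_SHARED) {
        k2$shared[cn] <- k2$shared[cn] * f
      } else {
        k2$perfa[cn, fas] <- k2$perfa[cn, fas] * f
      }
      ct <- tryCatch(class_totals(simulate_oxidation(config, k2)),
                     error = function(e) NULL)
      if (is.null(ct)) { failed <- TRUE; break }
      for (cls in classes) {
        if (rngs[cls] <= 0) next
        val <- sqrt(mean((ct[[cls]] - ref[[cls]])^2)) / rngs[cls]
        map[[paste(cn, f, cls)]] <<- val
        worst <- max(worst, val)
      }
    }
    data.frame(constant = cn,
               max_nrmse = if (failed) Inf else worst,
               insensitive = !failed && worst < threshold,
               failed = failed)
  })
  out <- do.call(rbind, rows)
  attr(out, "map") <- map
  attr(out, "threshold") <- threshold
  class(out) <- c("ox_sa", class(out))
  out
}

#' Recover an NMR-acquisition correction constant
#'
#' Given an observed product curve containing the acquisition artefact
#' and the base model curve without it, the correction constant is the
#' least-squares slope of the excess product against the LOOH increase
#' (the proportional-formation model integrates to
#' `obs(t) - base(t) = alpha * (LOOH(t) - LOOH(0))`).
#'
#' @param obs Observed product curve (e.g. ALD totals).
#' @param base Model product curve with the correction disabled.
#' @param looh LOOH total curve from the same simulation.
#' @return The estimated alpha (dimensionless).
#' @export
fit_alpha_constant <- function(obs, base, looh) {
  stopifnot(length(obs) == length(base), length(obs) == length(looh))
  dl <- looh - looh[1]
  if (sum(dl^2) <= 0) stop("LOOH curve shows no change; alpha unidentifiable")
  sum((obs - base) * dl) / sum(dl^2)
}

#' Recover both correction constants from paired trajectories
#'
#' @param traj_obs Trajectory simulated with the correction enabled (or
#'   observed data mapped onto the same grid).
#' @param traj_base Trajectory with the correction disabled, same
#'   config otherwise.
#' @return Named vector `alpha_ALD`, `alpha_LOH`.
#' @export
estimate_alpha <- function(traj_obs, traj_base) {
  co <- class_totals(traj_obs)
  cb <- class_totals(traj_base)
  stopifnot(nrow(co) == nrow(cb))
  c(alpha_ALD = fit_alpha_constant(co$ALD, cb$ALD, co$LOOH),
    alpha_LOH = fit_alpha_constant(co$LOH, cb$LOH, co$LOOH))
}
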