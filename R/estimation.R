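# Estimation of the sorption coefficient and the biodegradation rate
# constant from paired sterile-control / biotic column breakthrough curves.
# The estimation order mirrors the column study design: sorption from the
# sterile control (decay known 0), then decay with sorption fixed.

new_estimation_result <- function(estimates, objective, convergence, trace,
                                  fitted, residuals, data, refit, settings,
                                  warnings = character(0)) {
  structure(list(estimates = estimates, objective = objective,
                 convergence = convergence, trace = trace,
                 fitted = fitted, residuals = residuals, data = data,
                 refit = refit, settings = settings, warnings = warnings,
                 intervals = NULL),
            class = "estimation_result")
}

#' @method print estimation_result
#' @export
print.estimation_result <- function(x, ...) {
  cat("Estimation result\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.6g\n", nm, x$estimates[[nm]]))
  cat(sprintf("  objective (SSR) = %.4g (mg/L)^2, converged: %s\n",
              x$objective, x$convergence))
  if (!is.null(x$intervals)) {
    for (nm in rownames(x$intervals))
      cat(sprintf("  %s bootstrap CI: [%.6g, %.6g]\n", nm,
                  x$intervals[nm, 1], x$intervals[nm, 2]))
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

# bounded 1-D least squares with 3 log-spaced multi-starts; the bracket
# around the best start is refined with golden-section search, widening to
# the full bounds if the refinement lands on a bracket edge. Returns the
# estimate plus the accepted (best-so-far) trace.
scalar_ls_fit <- function(obj, bounds, n_starts = 3, tol = 1e-10) {
  lo <- bounds[1]; hi <- bounds[2]
  starts <- exp(seq(log(max(lo, hi * 1e-4)), log(hi), length.out = n_starts))
  trace <- data.frame(value = numeric(0), objective = numeric(0),
                      best = numeric(0))
  best_obj <- Inf
  f_traced <- function(p) {
    val <- obj(p)
    best_obj <<- min(best_obj, val)
    trace[nrow(trace) + 1, ] <<- c(p, val, best_obj)
    val
  }
  start_obj <- vapply(starts, f_traced, numeric(1))
  # bracket around the best start (ties: smallest parameter)
  i <- which(start_obj == min(start_obj))[1]
  lo_i <- if (i == 1) lo else starts[i - 1]
  hi_i <- if (i == n_starts) hi else starts[i + 1]
  opt <- optimize(f_traced, lower = lo_i, upper = hi_i, tol = tol)
  edge <- min(opt$minimum - lo_i, hi_i - opt$minimum) <
    1e-3 * (hi_i - lo_i)
  if (edge && (lo_i > lo || hi_i < hi)) {
    opt_full <- optimize(f_traced, lower = lo, upper = hi, tol = tol)
    if (opt_full$objective < opt$objective) opt <- opt_full
  }
  flat <- (max(start_obj) - min(start_obj)) <=
    1e-10 * max(abs(start_obj), 1e-300)
  list(estimate = opt$minimum, objective = opt$objective, trace = trace,
       flat = flat)
}

#' Estimate the sorption coefficient from a sterile control BTC
#'
#' Minimises the unweighted sum of squared concentration residuals between
#' the forward column model and the observed sterile-control breakthrough
#' curve over the sorption distribution coefficient `Kd`, with decay fixed
#' at zero and the dispersivity and kinetic sorption rate supplied (the
#' dispersivity typically from [fit_tracer()]). Bounded scalar search from
#' three log-spaced starts; the accepted-trace of best-so-far objectives is
#' recorded.
#'
#' @param btc_control Sterile-control [breakthrough_curve()].
#' @param spec The control [column_spec()].
#' @param inlet The [inlet_schedule()] (influent concentration history).
#' @param dispersivity Longitudinal dispersivity (m), held fixed.
#' @param sorption_rate Kinetic sorption rate alpha (1/d), held fixed;
#'   `Inf` for equilibrium sorption.
#' @param bounds Search interval for `Kd` (m^3/kg).
#' @param nx,courant Numerics passed to [simulate_column()].
#' @param tol Optimizer tolerance on the parameter.
#' @return An `estimation_result` with `estimates$sorption_coeff` (m^3/kg),
#'   the objective value, an optimizer trace, residuals, and a `refit`
#'   closure used by [bootstrap_ci()]. An identifiability warning is
#'   recorded if the objective is flat across the starts.
#' @export
fit_sorption <- function(btc_control, spec, inlet, dispersivity = 0.005,
                         sorption_rate = 1e-4, bounds = c(0, 0.5),
                         nx = 200, courant = 0.5, tol = 1e-10) {
  stopifnot(inherits(btc_control, "breakthrough_curve"),
            inherits(spec, "column_spec"),
            inherits(inlet, "inlet_schedule"))
  forward <- function(Kd, times) {
    pars <- column_transport_params(spec, dispersivity = dispersivity,
                                    sorption_coeff = Kd,
                                    sorption_rate = sorption_rate, decay = 0)
    sim <- simulate_column(spec, pars, inlet, nx = nx, courant = courant,
                           sample_times = times,
                           duration = max(times))
    sim$btc$conc_mg_per_L
  }
  run <- function(conc) {
    obj <- function(Kd) sum((forward(Kd, btc_control$time_d) - conc)^2)
    scalar_ls_fit(obj, bounds, tol = tol)
  }
  fit <- run(btc_control$conc_mg_per_L)
  warn <- character(0)
  if (fit$flat)
    warn <- "objective insensitive to Kd across starts (identifiability)"
  fitted <- forward(fit$estimate, btc_control$time_d)
  new_estimation_result(
    estimates = list(sorption_coeff = fit$estimate),
    objective = fit$objective, convergence = TRUE, trace = fit$trace,
    fitted = fitted, residuals = btc_control$conc_mg_per_L - fitted,
    data = btc_control,
    refit = function(conc) run(conc)$estimate,
    settings = list(dispersivity = dispersivity,
                    sorption_rate = sorption_rate, bounds = bounds,
                    nx = nx, courant = courant),
    warnings = warn)
}

#' Estimate the biodegradation rate constant from a biotic/control BTC pair
#'
#' With the sorption parameters fixed (normally from [fit_sorption()] on the
#' sterile control), minimises the unweighted sum of squared residuals of
#' the biotic breakthrough curve — or, with `objective = "difference"`, of
#' the control-minus-biotic difference series interpolated onto the biotic
#' sampling times — over the first-order decay constant `k`.
#'
#' @param btc_biotic Biotic-column [breakthrough_curve()].
#' @param btc_control Optional control curve; used for the sign check and
#'   for the `"difference"` objective.
#' @param spec The biotic [column_spec()].
#' @param inlet The [inlet_schedule()].
#' @param dispersivity,sorption_coeff,sorption_rate Fixed transport and
#'   sorption parameters.
#' @param spec_control Optional control [column_spec()] for the
#'   `"difference"` objective (defaults to `spec`).
#' @param objective `"biotic"` (default) or `"difference"`.
#' @param bounds Search interval for `k` (1/d).
#' @param nx,courant Numerics passed to [simulate_column()].
#' @param tol Optimizer tolerance on the parameter.
#' @return An `estimation_result` with `estimates$decay` (1/d). If the
#'   biotic curve lies above the control beyond noise a sign warning is
#'   recorded (no degradation signal).
#' @export
fit_decay <- function(btc_biotic, btc_control = NULL, spec, inlet,
                      dispersivity = 0.005, sorption_coeff = 0.068,
                      sorption_rate = 1e-4, spec_control = NULL,
                      objective = c("biotic", "difference"),
                      bounds = c(0, 0.05), nx = 200, courant = 0.5,
                      tol = 1e-10) {
  stopifnot(inherits(btc_biotic, "breakthrough_curve"),
            inherits(spec, "column_spec"),
            inherits(inlet, "inlet_schedule"))
  objective <- match.arg(objective)
  if (objective == "difference" && is.null(btc_control))
    stop("fit_decay: the difference objective needs btc_control")
  if (is.null(spec_control)) spec_control <- spec

  forward <- function(k, sp, times) {
    pars <- column_transport_params(sp, dispersivity = dispersivity,
                                    sorption_coeff = sorption_coeff,
                                    sorption_rate = sorption_rate, decay = k)
    sim <- simulate_column(sp, pars, inlet, nx = nx, courant = courant,
                           sample_times = times, duration = max(times))
    sim$btc$conc_mg_per_L
  }
  warn <- character(0)
  if (!is.null(btc_control)) {
    ctrl_on_biotic <- approx(btc_control$time_d, btc_control$conc_mg_per_L,
                             xout = btc_biotic$time_d, rule = 2)$y
    excess <- mean(btc_biotic$conc_mg_per_L - ctrl_on_biotic)
    spread <- sd(btc_biotic$conc_mg_per_L - ctrl_on_biotic)
    if (excess > spread / sqrt(nrow(btc_biotic)))
      warn <- c(warn, paste0("biotic curve above control beyond noise ",
                             "(no degradation signal)"))
  }
  times <- btc_biotic$time_d
  if (objective == "biotic") {
    yobs <- btc_biotic$conc_mg_per_L
    model <- function(k) forward(k, spec, times)
  } else {
    ctrl_on_biotic <- approx(btc_control$time_d, btc_control$conc_mg_per_L,
                             xout = times, rule = 2)$y
    yobs <- ctrl_on_biotic - btc_biotic$conc_mg_per_L
    model <- function(k) forward(0, spec_control, times) - forward(k, spec, times)
  }
  run <- function(y) {
    obj <- function(k) sum((model(k) - y)^2)
    scalar_ls_fit(obj, bounds, tol = tol)
  }
  fit <- run(yobs)
  if (fit$flat)
    warn <- c(warn, "objective insensitive to k across starts")
  fitted <- model(fit$estimate)
  new_estimation_result(
    estimates = list(decay = fit$estimate),
    objective = fit$objective, convergence = TRUE, trace = fit$trace,
    fitted = fitted, residuals = yobs - fitted, data = btc_biotic,
    refit = function(y) run(y)$estimate,
    settings = list(dispersivity = dispersivity,
                    sorption_coeff = sorption_coeff,
                    sorption_rate = sorption_rate, objective = objective,
                    bounds = bounds, nx = nx, courant = courant),
    warnings = warn)
}

#' Quasi-steady closed-form decay estimate from plateau concentrations
#'
#' Once both columns have reached a stable effluent plateau the sorption
#' flux vanishes and the plug-flow steady state gives
#' `k = ln(c_control / c_biotic) / t_res`. Used as an arithmetic cross-check
#' of the least-squares estimate over the quasi-steady pore-volume window.
#'
#' @param c_control_ss,c_biotic_ss Plateau effluent concentrations (mg/L),
#'   both `> 0`, with `c_control_ss >= c_biotic_ss`.
#' @param t_res Hydraulic residence time (d).
#' @return Decay rate (1/d).
#' @export
quasi_steady_k <- function(c_control_ss, c_biotic_ss, t_res) {
  if (any(c_control_ss <= 0))
    stop("quasi_steady_k: control concentration must be > 0")
  if (any(c_biotic_ss < c_control_ss * 1e-12) || any(c_biotic_ss <= 0))
    stop("quasi_steady_k: biotic concentration too close to zero ",
         "(estimate would overflow)")
  if (any(c_biotic_ss > c_control_ss * (1 + 1e-12)))
    stop("quasi_steady_k: biotic concentration exceeds control ",
         "(no attenuation signal)")
  if (any(t_res <= 0)) stop("quasi_steady_k: t_res must be > 0")
  log(c_control_ss / c_biotic_ss) / t_res
}

#' Residual-resampling bootstrap intervals for a fitted parameter
#'
#' Resamples the fit residuals with replacement, adds them to the fitted
#' curve (truncating at zero concentration), re-runs the estimator via the
#' `refit` closure stored in the `estimation_result`, and returns
#' percentile intervals. Deterministic under a fixed seed.
#'
#' @param result An `estimation_result` from [fit_sorption()] or
#'   [fit_decay()].
#' @param n_boot Number of bootstrap replicates (at least 50).
#' @param seed Integer seed.
#' @param level Interval coverage level.
#' @return The `estimation_result` with an `intervals` matrix (one row per
#'   parameter, columns `lower`/`upper`) and the bootstrap draws attached as
#'   `boot_estimates`.
#' @export
bootstrap_ci <- function(result, n_boot = 200, seed = 1, level = 0.95) {
  stopifnot(inherits(result, "estimation_result"))
  if (n_boot < 50)
    stop("bootstrap_ci: n_boot must be at least 50 for stable percentiles")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n <- length(result$residuals)
  draws <- vapply(seq_len(n_boot), function(b) {
    y_star <- result$fitted + sample(result$residuals, n, replace = TRUE)
    y_star <- pmax(y_star, 0)
    result$refit(y_star)
  }, numeric(1))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- matrix(quantile(draws, probs, names = FALSE), nrow = 1,
               dimnames = list(names(result$estimates)[1],
                               c("lower", "upper")))
  result$intervals <- ci
  result$boot_estimates <- draws
  result
}
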