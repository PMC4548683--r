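# Synthetic data generation: column and tracer breakthrough curves with
# realistic measurement noise, and a synthetic contaminated site anchored at
# monitoring-well concentrations. Every generator records its seed and the
# generating truth alongside the data, so round-trip recovery is testable.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic column-experiment scenario
#'
#' Describes the data-generating conditions of the paired-column study used
#' throughout: two packed columns (biotic and sterile control, see
#' [tca_column_spec()]), a stock influent of 31.36 mg/L TCA with a
#' reservoir-to-reservoir standard deviation of 1.87 mg/L, 25 days of
#' operation at 0.1 mL/min with effluent sampling every 2 days, and additive
#' Gaussian measurement noise (default 5% of the influent mean, truncated at
#' zero). The generating truth is a [transport_params()]-style set:
#' dispersivity 0.005 m, sorption coefficient 0.068 m^3/kg with kinetic rate
#' 1e-4 1/d, and biodegradation rate 0.0045 1/d.
#'
#' @param spec_biotic,spec_control Column specifications.
#' @param dispersivity Longitudinal dispersivity (m).
#' @param sorption_coeff True sorption coefficient (m^3/kg).
#' @param sorption_rate True kinetic sorption rate (1/d; `Inf` equilibrium).
#' @param decay True biodegradation rate in the biotic column (1/d).
#' @param c0_mean,c0_sd Influent concentration mean and reservoir s.d.
#'   (mg/L); the reservoir value is drawn once per experiment.
#' @param duration Operation time (d).
#' @param sampling_interval Effluent sampling interval (d); samples are
#'   taken at `seq(sampling_interval/2 ...)`-style odd days so the final
#'   sample falls on the last day (1, 3, ..., 25 by default).
#' @param noise_sd Measurement noise s.d. (mg/L).
#' @param nx,courant Numerics for the forward runs.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(spec_biotic = tca_column_spec(1),
                               spec_control = tca_column_spec(2),
                               dispersivity = 0.005,
                               sorption_coeff = 0.068,
                               sorption_rate = 1e-4,
                               decay = 0.0045,
                               c0_mean = 31.36, c0_sd = 1.87,
                               duration = 25, sampling_interval = 2,
                               noise_sd = 0.05 * c0_mean,
                               nx = 200, courant = 0.5) {
  if (duration <= 0) stop("synthetic_scenario: duration must be > 0")
  if (noise_sd < 0 || c0_sd < 0)
    stop("synthetic_scenario: noise must be >= 0")
  structure(list(spec_biotic = spec_biotic, spec_control = spec_control,
                 dispersivity = dispersivity,
                 sorption_coeff = sorption_coeff,
                 sorption_rate = sorption_rate, decay = decay,
                 c0_mean = c0_mean, c0_sd = c0_sd, duration = duration,
                 sampling_interval = sampling_interval,
                 noise_sd = noise_sd, nx = nx, courant = courant),
            class = "synthetic_scenario")
}

scenario_sample_times <- function(scenario) {
  seq(scenario$sampling_interval / 2, scenario$duration,
      by = scenario$sampling_interval)
}

#' Generate a synthetic column breakthrough curve
#'
#' Runs the forward column model under the scenario truth (decay forced to
#' zero for the sterile control), samples the effluent on the scenario's
#' schedule, perturbs the influent concentration by one reservoir draw
#' (when `c0_sd > 0`), adds Gaussian measurement noise and truncates at
#' zero. The generating truth (including the realised influent and the
#' seed) is attached as `attr(btc, "truth")`.
#'
#' @param scenario A [synthetic_scenario()].
#' @param sterile Logical; `TRUE` generates the control column (decay 0).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return A [breakthrough_curve()] with a `truth` attribute.
#' @export
generate_column_btc <- function(scenario, sterile = FALSE, seed = 1) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(seed, {
    spec <- if (sterile) scenario$spec_control else scenario$spec_biotic
    C0 <- scenario$c0_mean +
      if (scenario$c0_sd > 0) rnorm(1, 0, scenario$c0_sd) else 0
    C0 <- max(C0, 0)
    k <- if (sterile) 0 else scenario$decay
    pars <- column_transport_params(
      spec, dispersivity = scenario$dispersivity,
      sorption_coeff = scenario$sorption_coeff,
      sorption_rate = scenario$sorption_rate, decay = k)
    times <- scenario_sample_times(scenario)
    sim <- simulate_column(spec, pars, constant_inlet(C0, scenario$duration),
                           nx = scenario$nx, courant = scenario$courant,
                           sample_times = times)
    conc <- sim$btc$conc_mg_per_L
    if (scenario$noise_sd > 0)
      conc <- conc + rnorm(length(conc), 0, scenario$noise_sd)
    conc <- pmax(conc, 0)
    btc <- breakthrough_curve(times, conc, spec = spec,
                              analyte = "TCA", column_id = spec$column_id)
    attr(btc, "truth") <- list(
      sorption_coeff = scenario$sorption_coeff,
      sorption_rate = scenario$sorption_rate, decay = k,
      dispersivity = scenario$dispersivity, influent = C0,
      noise_sd = scenario$noise_sd, sterile = sterile, seed = seed)
    btc
  })
}

#' Generate a synthetic conservative tracer breakthrough curve
#'
#' Simulates a NaCl step input (default 3 g/L for 3 pore volumes at the
#' column flow rate), samples the effluent densely, and adds Gaussian noise
#' truncated at zero. Concentrations are reported in g/L.
#'
#' @param spec A [column_spec()].
#' @param dispersivity Generating dispersivity (m).
#' @param conc Tracer feed concentration (g/L).
#' @param pulse_pv Feed duration in pore volumes.
#' @param sampling_interval Sampling interval (d).
#' @param noise_sd Noise s.d. (g/L).
#' @param seed Integer seed.
#' @param nx,courant Numerics for the forward run.
#' @return A [breakthrough_curve()] (analyte `"NaCl"`, units g/L) with a
#'   `truth` attribute.
#' @export
generate_tracer_btc <- function(spec, dispersivity = 0.005, conc = 3,
                                pulse_pv = 3, sampling_interval = 0.25,
                                noise_sd = 0, seed = 1,
                                nx = 200, courant = 0.5) {
  stopifnot(inherits(spec, "column_spec"))
  with_seed(seed, {
    duration <- pulse_pv * residence_time(spec)
    pars <- column_transport_params(spec, dispersivity = dispersivity,
                                    sorption_coeff = 0, decay = 0)
    times <- seq(sampling_interval, duration, by = sampling_interval)
    sim <- simulate_column(spec, pars, constant_inlet(conc, duration),
                           nx = nx, courant = courant, sample_times = times)
    cc <- sim$btc$conc_mg_per_L
    if (noise_sd > 0) cc <- cc + rnorm(length(cc), 0, noise_sd)
    cc <- pmax(cc, 0)
    btc <- breakthrough_curve(times, cc, spec = spec, analyte = "NaCl",
                              column_id = spec$column_id)
    attr(btc, "truth") <- list(dispersivity = dispersivity,
                               porosity = spec$porosity, conc = conc,
                               noise_sd = noise_sd, seed = seed)
    btc
  })
}

#' Default monitoring-well anchors for the synthetic site
#'
#' Three wells anchoring the initial plume: the two source-area wells
#' (49.70 mg/L screened at 2-4 m, 22.00 mg/L at 4-6 m) and a down-gradient
#' well at 0.297 mg/L. Well coordinates on the synthetic grid are invented
#' (the real site layout is not published); concentrations are the reported
#' field values.
#'
#' @return Data frame with columns `well_id`, `row`, `col`, `layer`,
#'   `conc_mg_per_L`.
#' @export
default_monitoring_wells <- function() {
  data.frame(
    well_id = c("MW-3", "MW-5-4m", "MW-104"),
    row = c(48, 54, 30),
    col = c(42, 50, 70),
    layer = c(2, 3, 2),
    conc_mg_per_L = c(49.70, 22.00, 0.297),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic contaminated site
#'
#' Builds a [site_model()] and an initial plume as a sum of Gaussian
#' kernels centred at the anchor wells, with kernel weights solved so the
#' concentration at each anchor cell equals the anchor value exactly
#' (before any later noise). Horizontal length scale `length_scale`,
#' vertical length scale `vertical_scale`.
#'
#' @param anchors Data frame as [default_monitoring_wells()]; at least one
#'   anchor inside the grid.
#' @param site A [site_model()]; default the 100 m x 100 m, 4-layer site.
#' @param length_scale Horizontal kernel scale (m).
#' @param vertical_scale Vertical kernel scale (m).
#' @param seed Recorded seed (the construction itself is deterministic).
#' @return An object of class `synthetic_site`: `site`, `initial` (a
#'   [plume_state()]), `anchors`, `seed`.
#' @export
generate_site <- function(anchors = default_monitoring_wells(),
                          site = site_model(), length_scale = 8,
                          vertical_scale = 2, seed = 1) {
  stopifnot(inherits(site, "site_model"), nrow(anchors) >= 1)
  if (any(anchors$row < 1 | anchors$row > site$ny |
            anchors$col < 1 | anchors$col > site$nx |
            anchors$layer < 1 | anchors$layer > site$nlayers))
    stop("generate_site: anchor outside the model grid")
  xs <- (seq_len(site$nx) - 0.5) * site$dx
  ys <- (seq_len(site$ny) - 0.5) * site$dy
  zs <- cumsum(site$thickness) - site$thickness / 2
  m <- nrow(anchors)
  ax <- xs[anchors$col]; ay <- ys[anchors$row]; az <- zs[anchors$layer]
  kern_at <- function(x, y, z, j) {
    exp(-((x - ax[j])^2 + (y - ay[j])^2) / (2 * length_scale^2) -
          (z - az[j])^2 / (2 * vertical_scale^2))
  }
  # weights so that the field matches the anchors at their cells
  Kmat <- matrix(0, m, m)
  for (a in seq_len(m)) for (j in seq_len(m))
    Kmat[a, j] <- kern_at(ax[a], ay[a], az[a], j)
  w <- solve(Kmat, anchors$conc_mg_per_L)
  conc <- array(0, c(site$ny, site$nx, site$nlayers))
  for (k in seq_len(site$nlayers)) {
    gx <- matrix(rep(xs, each = site$ny), site$ny, site$nx)
    gy <- matrix(rep(ys, site$nx), site$ny, site$nx)
    layer <- matrix(0, site$ny, site$nx)
    for (j in seq_len(m))
      layer <- layer + w[j] * kern_at(gx, gy, zs[k], j)
    conc[, , k] <- layer
  }
  conc <- pmax(conc, 0)
  structure(list(site = site,
                 initial = plume_state(conc, time = 0),
                 anchors = anchors, length_scale = length_scale,
                 vertical_scale = vertical_scale, seed = seed),
            class = "synthetic_site")
}

#' @method print synthetic_site
#' @export
print.synthetic_site <- function(x, ...) {
  cat(sprintf("Synthetic site: %d anchors on a %d x %d x %d grid, max %.4g mg/L\n",
              nrow(x$anchors), x$site$ny, x$site$nx, x$site$nlayers,
              max(x$initial$conc)))
  invisible(x)
}

#' Generate synthetic monitoring-well observations from a forecast
#'
#' Samples the simulated concentration at each well cell and time, adds
#' Gaussian noise and clips at zero — a synthetic twin for
#' [compare_wells()].
#'
#' @param forecast A `plume_forecast` from [simulate_plume()].
#' @param wells Data frame with `well_id`, `row`, `col`, `layer`.
#' @param times Observation times (d), within the forecast span.
#' @param noise_sd Noise s.d. (mg/L).
#' @param seed Integer seed.
#' @return Data frame of observations (`well_id`, `row`, `col`, `layer`,
#'   `time_d`, `conc_mg_per_L`) with the seed attached as an attribute.
#' @export
generate_well_observations <- function(forecast, wells, times,
                                       noise_sd = 0, seed = 1) {
  stopifnot(inherits(forecast, "plume_forecast"))
  st_times <- vapply(forecast$states, function(s) s$time, numeric(1))
  if (max(times) > max(st_times) + 1e-9)
    stop("generate_well_observations: times beyond the simulated range")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(wells)), function(r) {
      series <- vapply(forecast$states,
                       function(s) s$conc[wells$row[r], wells$col[r],
                                          wells$layer[r]], numeric(1))
      sim <- approx(st_times, series, xout = times, rule = 2)$y
      obs <- pmax(sim + rnorm(length(times), 0, noise_sd), 0)
      data.frame(well_id = wells$well_id[r], row = wells$row[r],
                 col = wells$col[r], layer = wells$layer[r],
                 time_d = times, conc_mg_per_L = obs,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    out
  })
}
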