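# CSV input-output for breakthrough curves and the flat run configuration.
# BTC schema: time_d, pore_volumes, conc_mg_per_L, analyte, column_id;
# header row mandatory, '.' decimal separator, '#' comment lines allowed
# (the generators record their seed there).

#' Write a breakthrough curve to CSV
#'
#' @param btc A [breakthrough_curve()].
#' @param path Output file.
#' @param seed Optional seed recorded as a `# seed: <n>` comment header.
#' @return `path`, invisibly.
#' @export
write_btc <- function(btc, path, seed = NULL) {
  stopifnot(inherits(btc, "breakthrough_curve"))
  if (is.null(seed)) {
    truth <- attr(btc, "truth")
    if (!is.null(truth)) seed <- truth$seed
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# attenuate breakthrough curve, schema v1", con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.csv(as.data.frame(btc)[, c("time_d", "pore_volumes",
                                   "conc_mg_per_L", "analyte", "column_id")],
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a breakthrough curve from CSV
#'
#' Validates the schema: the required columns, strictly increasing times
#' and non-negative concentrations (errors cite the offending data row).
#' If the `pore_volumes` column is absent it is derived from `flow_rate`
#' and `pore_volume` (or a [column_spec()]).
#'
#' @param path CSV file (comment lines starting `#` are skipped).
#' @param spec Optional [column_spec()] used to derive pore volumes.
#' @param flow_rate,pore_volume Alternative to `spec`: flow (m^3/d) and
#'   pore volume (m^3).
#' @return A [breakthrough_curve()].
#' @export
read_btc <- function(path, spec = NULL, flow_rate = NULL,
                     pore_volume = NULL) {
  if (!file.exists(path)) stop("read_btc: file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("time_d", "conc_mg_per_L")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("read_btc: missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(diff(df$time_d) <= 0)
  if (length(bad))
    stop(sprintf("read_btc: time_d not strictly increasing at row %d",
                 bad[1] + 1))
  neg <- which(df$conc_mg_per_L < 0)
  if (length(neg))
    stop(sprintf("read_btc: negative concentration at row %d", neg[1]))
  if (is.null(df$pore_volumes)) {
    if (!is.null(spec)) {
      flow_rate <- spec$flow_rate
      pore_volume <- attenuate::pore_volume(spec)
    }
    if (is.null(flow_rate) || is.null(pore_volume))
      stop("read_btc: pore_volumes column absent; supply spec or ",
           "flow_rate + pore_volume to derive it")
    df$pore_volumes <- df$time_d * flow_rate / pore_volume
  }
  if (is.null(df$analyte)) df$analyte <- "TCA"
  if (is.null(df$column_id)) df$column_id <- "column"
  breakthrough_curve(df$time_d, df$conc_mg_per_L,
                     pore_volumes = df$pore_volumes,
                     analyte = df$analyte, column_id = df$column_id)
}

#' Default run configuration
#'
#' The flat key set understood by [read_run_config()] and the command-line
#' pipeline. Keys (units in the names): column geometry and packing,
#' transport truth/starting values, inlet, sampling, noise, site forecast
#' settings, numerics and the seed.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    column_length_m = 0.30,
    column_diameter_m = 0.10,
    porosity = 0.296,
    porosity_control = 0.289,
    bulk_density_kg_m3 = 1850,
    bulk_density_control_kg_m3 = 1880,
    flow_rate_mL_min = 0.1,
    dispersivity_m = 0.005,
    sorption_coeff_m3_kg = 0.068,
    sorption_rate_per_d = 1e-4,
    decay_per_d = 0.0045,
    inlet_conc_mg_L = 31.36,
    inlet_conc_sd_mg_L = 1.87,
    duration_d = 25,
    sampling_interval_d = 2,
    noise_sd_mg_L = 0.05 * 31.36,
    tracer_conc_g_L = 3,
    tracer_pulse_pv = 3,
    site_nx = 100, site_ny = 100, site_nlayers = 4,
    site_head_west_m = 10.05, site_head_east_m = 10.00,
    site_retardation = 1.425,
    site_dispersivity_long_m = 1.0,
    site_dispersivity_trans_m = 0.1,
    site_output_times_d = c(1, 183, 365, 730, 1825),
    nx = 200,
    courant = 0.5,
    seed = 1
  )
}

#' Read and validate a flat YAML run configuration
#'
#' Unknown keys are rejected (misspelled settings fail loudly rather than
#' being silently ignored); known keys override the defaults from
#' [default_config()].
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list: the fully resolved configuration.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  user <- yaml::read_yaml(path)
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("read_run_config: unknown key(s): ",
           paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  cfg
}

config_scenario <- function(cfg, noiseless = FALSE) {
  spec1 <- column_spec(cfg$column_length_m, cfg$column_diameter_m,
                       cfg$porosity, cfg$bulk_density_kg_m3,
                       ml_per_min(cfg$flow_rate_mL_min), "column_1")
  spec2 <- column_spec(cfg$column_length_m, cfg$column_diameter_m,
                       cfg$porosity_control, cfg$bulk_density_control_kg_m3,
                       ml_per_min(cfg$flow_rate_mL_min), "column_2")
  synthetic_scenario(
    spec_biotic = spec1, spec_control = spec2,
    dispersivity = cfg$dispersivity_m,
    sorption_coeff = cfg$sorption_coeff_m3_kg,
    sorption_rate = cfg$sorption_rate_per_d,
    decay = cfg$decay_per_d,
    c0_mean = cfg$inlet_conc_mg_L,
    c0_sd = if (noiseless) 0 else cfg$inlet_conc_sd_mg_L,
    duration = cfg$duration_d,
    sampling_interval = cfg$sampling_interval_d,
    noise_sd = if (noiseless) 0 else cfg$noise_sd_mg_L,
    nx = cfg$nx, courant = cfg$courant)
}
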