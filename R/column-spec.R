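#' Physical description of a packed laboratory column
#'
#' Bundles the geometry, packing and flow settings of a saturated,
#' upflow-operated soil column. All quantities are SI except where noted.
#'
#' @param length Column length (m).
#' @param inner_diameter Inner diameter (m).
#' @param porosity Effective porosity (dimensionless, in (0, 1)).
#' @param bulk_density Dry bulk density of the packing (kg/m^3).
#' @param flow_rate Volumetric flow rate (m^3/d). See [ml_per_min()] for a
#'   convenience converter from mL/min.
#' @param column_id Label used in breakthrough-curve output.
#' @param temperature_note Free-text note on the operating temperature.
#'
#' @return An object of class `column_spec`.
#' @seealso [pore_volume()], [residence_time()], [tca_column_spec()]
#' @examples
#' spec <- column_spec(length = 0.30, inner_diameter = 0.10, porosity = 0.296,
#'                     bulk_density = 1850, flow_rate = ml_per_min(0.1))
#' pore_volume(spec) * 1e6   # cm^3
#' residence_time(spec)      # d
#' @export
column_spec <- function(length, inner_diameter, porosity, bulk_density,
                        flow_rate, column_id = "column",
                        temperature_note = "") {
  stopifnot(is.numeric(length), is.numeric(inner_diameter),
            is.numeric(porosity), is.numeric(bulk_density),
            is.numeric(flow_rate))
  if (length <= 0 || inner_diameter <= 0)
    stop("invalid column_spec: length and inner_diameter must be > 0")
  if (porosity <= 0 || porosity >= 1)
    stop("invalid column_spec: porosity must lie strictly in (0, 1)")
  if (bulk_density <= 0)
    stop("invalid column_spec: bulk_density must be > 0")
  if (flow_rate <= 0)
    stop("invalid column_spec: flow_rate must be > 0")
  structure(list(length = length, inner_diameter = inner_diameter,
                 porosity = porosity, bulk_density = bulk_density,
                 flow_rate = flow_rate, column_id = as.character(column_id),
                 temperature_note = temperature_note),
            class = "column_spec")
}

#' @method print column_spec
#' @export
print.column_spec <- function(x, ...) {
  cat("Packed column '", x$column_id, "'\n", sep = "")
  cat(sprintf("  length %.3g m, diameter %.3g m, porosity %.3f\n",
              x$length, x$inner_diameter, x$porosity))
  cat(sprintf("  bulk density %.0f kg/m^3, flow %.4g m^3/d (%.3g mL/min)\n",
              x$bulk_density, x$flow_rate, x$flow_rate / 1.44e-3))
  cat(sprintf("  pore volume %.0f cm^3, residence time %.2f d\n",
              pore_volume(x) * 1e6, residence_time(x)))
  invisible(x)
}

#' Convert a flow rate from mL/min to m^3/d
#'
#' @param x Flow rate in mL/min.
#' @return Flow rate in m^3/d.
#' @export
ml_per_min <- function(x) x * 1e-6 * 1440

#' Cross-sectional area of a column (m^2)
#' @param spec A [column_spec()].
#' @return Area in m^2.
#' @export
column_area <- function(spec) {
  stopifnot(inherits(spec, "column_spec"))
  pi * (spec$inner_diameter / 2)^2
}

#' Total pore volume of a packed column
#'
#' `pi (d/2)^2 L theta`, the water-filled volume of the column; one "pore
#' volume" of flow is the natural dimensionless time unit for breakthrough
#' curves.
#'
#' @param spec A [column_spec()].
#' @return Pore volume in m^3.
#' @export
pore_volume <- function(spec) {
  stopifnot(inherits(spec, "column_spec"))
  column_area(spec) * spec$length * spec$porosity
}

#' Mean hydraulic residence time of a column
#'
#' Pore volume divided by flow rate: the time needed to pass one pore volume.
#'
#' @param spec A [column_spec()].
#' @return Residence time in days.
#' @export
residence_time <- function(spec) {
  pore_volume(spec) / spec$flow_rate
}

#' Mean pore-water velocity in a column
#'
#' Darcy flux divided by porosity, `Q / (A theta)` (m/d).
#'
#' @param spec A [column_spec()].
#' @return Pore velocity in m/d.
#' @export
pore_velocity <- function(spec) {
  spec$flow_rate / (column_area(spec) * spec$porosity)
}

#' Column parameters of the 1,1,1-TCA column study
#'
#' Returns the published physical parameters of the two packed columns used
#' in the TCA natural-attenuation column study: 10 cm inner diameter, 30 cm
#' length, porosities 0.296 (column 1, biotic) and 0.289 (column 2, sterile
#' control), bulk densities 1.85 and 1.88 g/cm^3, operated at 0.1 mL/min.
#'
#' @param column 1 (biotic) or 2 (sterile control).
#' @return A [column_spec()].
#' @export
tca_column_spec <- function(column = 1) {
  column <- match.arg(as.character(column), c("1", "2"))
  if (column == "1") {
    column_spec(length = 0.30, inner_diameter = 0.10, porosity = 0.296,
                bulk_density = 1850, flow_rate = ml_per_min(0.1),
                column_id = "column_1", temperature_note = "20-25 C")
  } else {
    column_spec(length = 0.30, inner_diameter = 0.10, porosity = 0.289,
                bulk_density = 1880, flow_rate = ml_per_min(0.1),
                column_id = "column_2", temperature_note = "20-25 C")
  }
}

#' Transport parameter set for the 1-D column model
#'
#' The governing equation is
#' \deqn{\theta \frac{\partial c}{\partial t} =
#'   \frac{\partial}{\partial x}\left(\theta D \frac{\partial c}{\partial x}\right)
#'   - q \frac{\partial c}{\partial x}
#'   - \rho_b \frac{\partial s}{\partial t} - \theta k c, \qquad
#'   \rho_b \frac{\partial s}{\partial t} = \rho_b\,\alpha (K_d c - s)}
#' with pore velocity \eqn{v = q/\theta}, dispersion
#' \eqn{D = a_L v + D_m}, one-site kinetic linear sorption (rate
#' \eqn{\alpha}, distribution coefficient \eqn{K_d}) and first-order decay
#' \eqn{k} acting on the aqueous phase only. `sorption_rate = Inf` is the
#' equilibrium sentinel: sorption is then instantaneous and enters as the
#' retardation factor \eqn{R = 1 + \rho_b K_d / \theta}.
#'
#' @param pore_velocity Pore-water velocity v (m/d).
#' @param dispersivity Longitudinal dispersivity a_L (m). Ignored when
#'   `dispersion` is given directly.
#' @param dispersion Hydrodynamic dispersion coefficient D (m^2/d);
#'   default `dispersivity * pore_velocity + molecular_diffusion`.
#' @param sorption_coeff Linear distribution coefficient K_d (m^3/kg).
#' @param sorption_rate First-order kinetic sorption rate alpha (1/d);
#'   `Inf` selects equilibrium sorption.
#' @param decay First-order aqueous decay rate k (1/d); 0 encodes the
#'   sterile control.
#' @param bulk_density Bulk density rho_b (kg/m^3), needed by the sorption
#'   terms.
#' @param porosity Porosity theta (dimensionless).
#' @param molecular_diffusion Effective molecular diffusion (m^2/d).
#' @return An object of class `transport_params`.
#' @seealso [column_transport_params()] to derive v from a [column_spec()].
#' @export
transport_params <- function(pore_velocity, dispersivity = 0.005,
                             dispersion = NULL, sorption_coeff = 0,
                             sorption_rate = 1e-4, decay = 0,
                             bulk_density = 1850, porosity = 0.3,
                             molecular_diffusion = 0) {
  if (is.null(dispersion))
    dispersion <- dispersivity * pore_velocity + molecular_diffusion
  vals <- c(pore_velocity = pore_velocity, dispersion = dispersion,
            sorption_coeff = sorption_coeff, decay = decay)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("transport_params: pore_velocity, dispersion, sorption_coeff and ",
         "decay must be finite and >= 0")
  if (is.na(sorption_rate) || sorption_rate < 0)
    stop("transport_params: sorption_rate must be >= 0 (Inf = equilibrium)")
  structure(list(pore_velocity = pore_velocity, dispersion = dispersion,
                 dispersivity = dispersivity,
                 sorption_coeff = sorption_coeff,
                 sorption_rate = sorption_rate, decay = decay,
                 bulk_density = bulk_density, porosity = porosity),
            class = "transport_params")
}

#' Derive transport parameters from a column specification
#'
#' Computes the pore velocity from the column flow rate and geometry and
#' carries the column's porosity and bulk density into the parameter set.
#'
#' @param spec A [column_spec()].
#' @inheritParams transport_params
#' @return A [transport_params()] object.
#' @export
column_transport_params <- function(spec, dispersivity = 0.005,
                                    sorption_coeff = 0, sorption_rate = 1e-4,
                                    decay = 0, molecular_diffusion = 0) {
  transport_params(pore_velocity = pore_velocity(spec),
                   dispersivity = dispersivity,
                   sorption_coeff = sorption_coeff,
                   sorption_rate = sorption_rate, decay = decay,
                   bulk_density = spec$bulk_density,
                   porosity = spec$porosity,
                   molecular_diffusion = molecular_diffusion)
}

#' Equilibrium retardation factor implied by a parameter set
#'
#' `R = 1 + rho_b Kd / theta`.
#'
#' @param params A [transport_params()] object.
#' @return Retardation factor (dimensionless, >= 1).
#' @export
retardation <- function(params) {
  stopifnot(inherits(params, "transport_params"))
  1 + params$bulk_density * params$sorption_coeff / params$porosity
}

#' @method print transport_params
#' @export
print.transport_params <- function(x, ...) {
  mode <- if (is.infinite(x$sorption_rate)) "equilibrium" else "kinetic"
  cat("Transport parameters\n")
  cat(sprintf("  v = %.4g m/d, D = %.4g m^2/d\n", x$pore_velocity,
              x$dispersion))
  cat(sprintf("  sorption: Kd = %.4g m^3/kg, %s (alpha = %.4g 1/d), R = %.3g\n",
              x$sorption_coeff, mode, x$sorption_rate, retardation(x)))
  cat(sprintf("  decay k = %.4g 1/d\n", x$decay))
  invisible(x)
}

#' Piecewise-constant inlet concentration schedule
#'
#' @param start,end Segment boundaries (d); segments must be contiguous
#'   from 0 and non-overlapping.
#' @param concentration Inlet concentration per segment (mg/L, >= 0).
#' @return An object of class `inlet_schedule`.
#' @seealso [constant_inlet()]
#' @export
inlet_schedule <- function(start, end, concentration) {
  stopifnot(length(start) == length(end),
            length(start) == length(concentration))
  o <- order(start)
  start <- start[o]; end <- end[o]; concentration <- concentration[o]
  if (abs(start[1]) > 1e-12)
    stop("inlet_schedule: segments must start at time 0")
  if (any(end <= start))
    stop("inlet_schedule: each segment must have end > start")
  if (length(start) > 1 &&
      any(abs(start[-1] - end[-length(end)]) > 1e-9))
    stop("inlet_schedule: segments must be contiguous and non-overlapping")
  if (any(concentration < 0))
    stop("inlet_schedule: concentrations must be >= 0")
  structure(data.frame(start = start, end = end,
                       concentration = concentration),
            class = c("inlet_schedule", "data.frame"))
}

#' Constant inlet schedule
#' @param concentration Inlet concentration (mg/L).
#' @param duration Duration (d).
#' @return An [inlet_schedule()] with one segment.
#' @export
constant_inlet <- function(concentration, duration) {
  inlet_schedule(0, duration, concentration)
}

#' Evaluate an inlet schedule at given times
#'
#' Right-continuous at segment boundaries; 0 after the last segment.
#'
#' @param inlet An [inlet_schedule()].
#' @param times Times (d).
#' @return Concentrations (mg/L).
#' @export
inlet_at <- function(inlet, times) {
  stopifnot(inherits(inlet, "inlet_schedule"))
  out <- numeric(length(times))
  for (j in seq_len(nrow(inlet))) {
    sel <- times >= inlet$start[j] - 1e-12 & times < inlet$end[j] - 1e-12
    out[sel] <- inlet$concentration[j]
  }
  # the final segment is closed on the right
  out[abs(times - inlet$end[nrow(inlet)]) <= 1e-12] <-
    inlet$concentration[nrow(inlet)]
  out
}

#' Total duration covered by an inlet schedule
#' @param inlet An [inlet_schedule()].
#' @return End time of the last segment (d).
#' @export
inlet_duration <- function(inlet) max(inlet$end)
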