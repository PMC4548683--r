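#' Breakthrough curve container
#'
#' A breakthrough curve (BTC) is the effluent concentration of an analyte at
#' the column outlet versus time, with the dimensionless pore-volume axis
#' alongside. Stored as a data frame with columns `time_d`, `pore_volumes`,
#' `conc_mg_per_L`, `analyte`, `column_id`.
#'
#' @param times Sampling times (d), strictly increasing.
#' @param concentrations Effluent concentrations (mg/L, >= 0).
#' @param spec Optional [column_spec()] used to compute pore volumes as
#'   `times * flow_rate / pore_volume(spec)`.
#' @param pore_volumes Pore volumes, if supplied directly.
#' @param analyte Analyte label (e.g. `"TCA"`, `"NaCl"`).
#' @param column_id Column label.
#' @return An object of class `breakthrough_curve` (also a data frame).
#' @export
breakthrough_curve <- function(times, concentrations, spec = NULL,
                               pore_volumes = NULL, analyte = "TCA",
                               column_id = "column") {
  stopifnot(length(times) == length(concentrations))
  if (length(times) == 0)
    stop("breakthrough_curve: empty curve")
  if (any(diff(times) <= 0))
    stop("breakthrough_curve: times must be strictly increasing")
  if (any(concentrations < 0))
    stop("breakthrough_curve: concentrations must be >= 0")
  if (is.null(pore_volumes)) {
    if (is.null(spec))
      stop("breakthrough_curve: supply either `spec` or `pore_volumes`")
    pore_volumes <- times * spec$flow_rate / pore_volume(spec)
    if (missing(column_id)) column_id <- spec$column_id
  }
  structure(data.frame(time_d = times, pore_volumes = pore_volumes,
                       conc_mg_per_L = concentrations,
                       analyte = analyte, column_id = column_id,
                       stringsAsFactors = FALSE),
            class = c("breakthrough_curve", "data.frame"))
}

#' @method print breakthrough_curve
#' @export
print.breakthrough_curve <- function(x, ...) {
  cat(sprintf("Breakthrough curve: %s at %s, %d samples, t = %.3g..%.3g d (%.3g..%.3g PV)\n",
              x$analyte[1], x$column_id[1], nrow(x),
              min(x$time_d), max(x$time_d),
              min(x$pore_volumes), max(x$pore_volumes)))
  print.data.frame(head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

#' @export
plot.breakthrough_curve <- function(x, pv = TRUE, ...) {
  xx <- if (pv) x$pore_volumes else x$time_d
  graphics::plot(xx, x$conc_mg_per_L,
                 xlab = if (pv) "pore volumes" else "time (d)",
                 ylab = "concentration (mg/L)",
                 main = paste(x$analyte[1], "breakthrough,", x$column_id[1]),
                 type = "b", ...)
  invisible(x)
}

#' Average a breakthrough curve over a pore-volume window
#'
#' Mean of the sampled concentrations whose pore volume falls in
#' `window` (inclusive within `tol`, so that samples whose PV rounds to the
#' printed window edges are captured).
#'
#' @param btc A [breakthrough_curve()].
#' @param window Pore-volume window, default `c(4.75, 5.16)` — the
#'   quasi-steady reporting window of the TCA column study.
#' @param tol Inclusion tolerance on the window edges (PV).
#' @return Mean concentration (mg/L).
#' @export
steady_window_mean <- function(btc, window = c(4.75, 5.16), tol = 0.005) {
  stopifnot(inherits(btc, "breakthrough_curve"), length(window) == 2)
  sel <- btc$pore_volumes >= window[1] - tol &
    btc$pore_volumes <= window[2] + tol
  if (!any(sel))
    stop("steady_window_mean: no samples inside the pore-volume window")
  mean(btc$conc_mg_per_L[sel])
}
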