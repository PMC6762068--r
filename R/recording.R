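#' Construct a flow recording
#'
#' A `flow_recording` holds one uniformly sampled multi-beat volumetric
#' flow-rate time series together with its sample rate and units. It is the
#' common currency between the simulator, the file readers and the
#' preprocessing chain.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing on a uniform grid.
#' @param values Numeric vector of flow-signal values (e.g. ml/s or raw ADC
#'   counts), same length as `times`.
#' @param sample_rate Sampling frequency in Hz. If `NULL` it is inferred from
#'   the median time step.
#' @param units Label for the signal units (default `"ml/s"`).
#' @param scenario Optional free-text scenario label (e.g. `"baseline"`,
#'   `"severe AR"`).
#'
#' @return An object of class `flow_recording` with fields `times`, `values`,
#'   `sample_rate`, `units` and `scenario`.
#' @export
flow_recording <- function(times, values, sample_rate = NULL, units = "ml/s",
                           scenario = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop_validation("times (%d) and values (%d) differ in length",
                    length(times), length(values))
  if (length(times) < 2L)
    stop_validation("a recording needs at least 2 samples")
  if (anyNA(times) || anyNA(values))
    stop_validation("recording contains missing values")
  dt <- diff(times)
  if (any(dt <= 0))
    stop_validation("times must be strictly increasing")
  dt_med <- stats::median(dt)
  if (any(abs(dt - dt_med) > 1e-6 * dt_med + 1e-12))
    stop_validation("non-uniform sampling: time steps deviate from %g s", dt_med)
  if (is.null(sample_rate)) sample_rate <- 1 / dt_med
  if (abs(dt_med - 1 / sample_rate) > 1e-6 / sample_rate)
    stop_validation("time grid spacing %g s does not match sample_rate %g Hz",
                    dt_med, sample_rate)
  structure(
    list(times = times, values = values, sample_rate = sample_rate,
         units = units, scenario = scenario),
    class = "flow_recording"
  )
}

#' @export
print.flow_recording <- function(x, ...) {
  cat(sprintf(
    "<flow_recording> %d samples @ %g Hz (%.2f s), units: %s%s\n",
    length(x$values), x$sample_rate,
    x$times[length(x$times)] - x$times[1], x$units,
    if (is.null(x$scenario)) "" else paste0(", scenario: ", x$scenario)))
  invisible(x)
}

#' @export
length.flow_recording <- function(x) length(x$values)
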