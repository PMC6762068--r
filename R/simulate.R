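# Pulsatile-flow simulator emulating an in-vitro aortic flow loop: a
# computer-controlled piston pump driving ~1 Hz pulsatile flow through a
# prosthetic valve, with tube inserts creating regurgitant leaks of graded
# severity. Stands in for the physical rig so the pipeline is testable
# without lab data.

RHO_BLOOD <- 1060      # kg/m^3
PA_PER_MMHG <- 101325 / 760
CLOSURE_FRACTION <- 0.08  # closure-reflux dip occupies this fraction of a cycle

#' Simulator configuration
#'
#' Collects and validates all parameters of the synthetic flow-loop
#' generator. Defaults reproduce the physiological resting condition of the
#' in-vitro rig the package emulates: cardiac output 5 l/min, 120/80 mmHg,
#' 60 beats/min, recordings of 1000 samples at 60 Hz (about 16 cycles).
#'
#' @param heart_rate Pump rate in beats/min (> 0).
#' @param cardiac_output Mean forward flow in l/min; the systolic ejection
#'   amplitude is normalized so the leak-free cycle mean equals this value.
#' @param systolic_fraction Fraction of the cycle occupied by ejection.
#' @param leak_area Regurgitant orifice area in mm^2; 0 gives the baseline
#'   (competent valve). The in-vitro inserts were 10.0, 31.4 and 99.4 mm^2
#'   for mild, moderate and severe regurgitation.
#' @param diastolic_pressure Trans-valvular pressure during diastole in mmHg;
#'   drives the leak through the orifice equation.
#' @param discharge_coefficient Orifice discharge coefficient (dimensionless).
#' @param closure_reflux_volume Backflow volume in ml of the brief
#'   valve-closure dip at end-systole (0 disables it).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise, in
#'   signal units (ml/s before any ADC mapping).
#' @param period_jitter_sd Cycle-to-cycle period standard deviation in
#'   seconds. Default 0: a piston pump shows no appreciable cycle-to-cycle
#'   variability. Exposed for robustness experiments.
#' @param sample_rate Sampling frequency in Hz.
#' @param n_samples Number of samples per recording; must cover at least two
#'   cardiac cycles.
#' @param adc_bits Optional quantization depth; when set, values are mapped
#'   through an affine ADC model (`adc_offset`, `adc_gain`, rounding, clipping
#'   to `[0, 2^adc_bits - 1]`) and reported as counts.
#' @param adc_offset,adc_gain Affine ADC mapping: `counts =
#'   round((q - adc_offset) / adc_gain)`. Defaults span roughly -200 to
#'   500 ml/s across the ADC range.
#' @param seed Optional integer seed; identical config + seed gives
#'   bit-identical recordings.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(heart_rate = 60, cardiac_output = 5.0,
                              systolic_fraction = 0.35, leak_area = 0,
                              diastolic_pressure = 80,
                              discharge_coefficient = 0.6,
                              closure_reflux_volume = 3,
                              noise_sd = 5, period_jitter_sd = 0,
                              sample_rate = 60, n_samples = 1000,
                              adc_bits = NULL, adc_offset = -200,
                              adc_gain = NULL, seed = NULL) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop_config("invalid config field '%s': %s", field, why)
  }
  chk(is.numeric(heart_rate) && heart_rate > 0, "heart_rate", "must be > 0")
  chk(is.numeric(cardiac_output) && cardiac_output > 0, "cardiac_output",
      "must be > 0")
  chk(is.numeric(systolic_fraction) && systolic_fraction > 0 &&
        systolic_fraction < 1 - CLOSURE_FRACTION, "systolic_fraction",
      sprintf("must lie in (0, %g)", 1 - CLOSURE_FRACTION))
  chk(is.numeric(leak_area) && leak_area >= 0, "leak_area", "must be >= 0")
  chk(is.numeric(diastolic_pressure) && diastolic_pressure > 0,
      "diastolic_pressure", "must be > 0")
  chk(is.numeric(discharge_coefficient) && discharge_coefficient > 0 &&
        discharge_coefficient <= 1, "discharge_coefficient",
      "must be in (0, 1]")
  chk(is.numeric(closure_reflux_volume) && closure_reflux_volume >= 0,
      "closure_reflux_volume", "must be >= 0")
  chk(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(is.numeric(period_jitter_sd) && period_jitter_sd >= 0,
      "period_jitter_sd", "must be >= 0")
  chk(is.numeric(sample_rate) && sample_rate > 0, "sample_rate", "must be > 0")
  chk(is.numeric(n_samples) && n_samples == round(n_samples),
      "n_samples", "must be an integer count")
  min_n <- 2 * sample_rate * 60 / heart_rate
  chk(n_samples >= min_n, "n_samples",
      sprintf("must cover >= 2 cardiac cycles (>= %g samples)", min_n))
  if (!is.null(adc_bits)) {
    chk(is.numeric(adc_bits) && adc_bits == round(adc_bits) && adc_bits >= 2,
        "adc_bits", "must be an integer >= 2")
    if (is.null(adc_gain)) adc_gain <- 700 / (2^adc_bits - 1)
    chk(is.numeric(adc_gain) && adc_gain > 0, "adc_gain", "must be > 0")
  }
  if (!is.null(seed))
    chk(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")

  structure(
    list(heart_rate = heart_rate, cardiac_output = cardiac_output,
         systolic_fraction = systolic_fraction, leak_area = leak_area,
         diastolic_pressure = diastolic_pressure,
         discharge_coefficient = discharge_coefficient,
         closure_reflux_volume = closure_reflux_volume,
         noise_sd = noise_sd, period_jitter_sd = period_jitter_sd,
         sample_rate = sample_rate, n_samples = as.integer(n_samples),
         adc_bits = adc_bits, adc_offset = adc_offset, adc_gain = adc_gain,
         seed = seed),
    class = "simulation_config"
  )
}

#' Diastolic leak flow through a regurgitant orifice
#'
#' Steady orifice equation `Q = C_d * A * sqrt(2 * dP / rho)` with blood
#' density 1060 kg/m^3; returns the leak magnitude in ml/s (the simulated
#' leak flow is `-orifice_leak_flow(...)`, i.e. retrograde).
#'
#' @param leak_area Orifice area in mm^2.
#' @param diastolic_pressure Driving pressure in mmHg.
#' @param discharge_coefficient Discharge coefficient.
#' @return Leak flow magnitude in ml/s.
#' @export
orifice_leak_flow <- function(leak_area, diastolic_pressure = 80,
                              discharge_coefficient = 0.6) {
  dp_pa <- diastolic_pressure * PA_PER_MMHG
  v <- sqrt(2 * dp_pa / RHO_BLOOD)              # m/s
  discharge_coefficient * leak_area * 1e-6 * v * 1e6  # m^3/s -> ml/s
}

#' Generate a synthetic flow recording
#'
#' Produces one multi-beat recording with, per cycle: a half-sine systolic
#' ejection whose amplitude is normalized so the leak-free cycle mean equals
#' the configured cardiac output; a brief negative half-sine closure-reflux
#' dip of the configured backflow volume; and a constant retrograde diastolic
#' leak from the orifice equation. Gaussian noise and optional ADC
#' quantization are applied last.
#'
#' @param config A [simulation_config()].
#' @param scenario Optional scenario label stored on the recording; defaults
#'   to a label derived from `leak_area`.
#' @return A [flow_recording()].
#' @export
#' @examples
#' rec <- generate_recording(simulation_config(seed = 1))
#' rec
generate_recording <- function(config, scenario = NULL) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  with_local_seed(config$seed, {
    T0 <- 60 / config$heart_rate
    duration <- config$n_samples / config$sample_rate
    n_cycles <- ceiling(duration / T0) + 2L
    periods <- rep(T0, n_cycles)
    if (config$period_jitter_sd > 0) {
      periods <- T0 + rnorm(n_cycles, 0, config$period_jitter_sd)
      periods <- pmax(periods, 0.2 * T0)
    }
    starts <- c(0, cumsum(periods))
    while (starts[length(starts)] < duration) {  # jitter may shorten coverage
      extra <- if (config$period_jitter_sd > 0)
        max(0.2 * T0, T0 + rnorm(1, 0, config$period_jitter_sd)) else T0
      periods <- c(periods, extra)
      starts <- c(starts, starts[length(starts)] + extra)
    }

    times <- (seq_len(config$n_samples) - 1) / config$sample_rate
    idx <- findInterval(times, starts)
    s <- times - starts[idx]          # time within the current cycle
    Tk <- periods[idx]
    co_mls <- config$cardiac_output * 1000 / 60

    q <- numeric(config$n_samples)
    ts_k <- config$systolic_fraction * Tk
    tc_k <- CLOSURE_FRACTION * Tk
    in_sys <- s < ts_k
    in_clo <- !in_sys & s < ts_k + tc_k
    # amplitude such that the leak-free mean over the cycle is cardiac output
    q_peak <- co_mls * pi / (2 * config$systolic_fraction)
    q[in_sys] <- q_peak * sin(pi * s[in_sys] / ts_k[in_sys])
    if (config$closure_reflux_volume > 0) {
      a_clo <- config$closure_reflux_volume * pi / (2 * tc_k[in_clo])
      q[in_clo] <- -a_clo * sin(pi * (s[in_clo] - ts_k[in_clo]) / tc_k[in_clo])
    }
    if (config$leak_area > 0) {
      q_leak <- orifice_leak_flow(config$leak_area, config$diastolic_pressure,
                                  config$discharge_coefficient)
      q[!in_sys & !in_clo] <- -q_leak
    }

    if (config$noise_sd > 0)
      q <- q + rnorm(config$n_samples, 0, config$noise_sd)

    units <- "ml/s"
    if (!is.null(config$adc_bits)) {
      q <- round((q - config$adc_offset) / config$adc_gain)
      q <- pmin(pmax(q, 0), 2^config$adc_bits - 1)
      units <- "ADC counts"
    }

    if (is.null(scenario))
      scenario <- if (config$leak_area == 0) "baseline"
        else sprintf("leak %.1f mm^2", config$leak_area)
    rec <- flow_recording(times, q, sample_rate = config$sample_rate,
                          units = units, scenario = scenario)
    rec$config <- config
    rec
  })
}

#' Generate a batch of recordings for one scenario
#'
#' Convenience wrapper drawing `n` independent recordings from one
#' configuration, with per-recording seeds derived from `config$seed`.
#'
#' @param config A [simulation_config()]; its `seed` anchors the batch.
#' @param n Number of recordings.
#' @return List of [flow_recording()] objects.
#' @export
generate_batch <- function(config, n) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  base_seed <- if (is.null(config$seed)) NULL else config$seed
  lapply(seq_len(n), function(i) {
    cfg <- config
    if (!is.null(base_seed))
      cfg$seed <- (base_seed * 1000L + i) %% .Machine$integer.max
    generate_recording(cfg)
  })
}
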