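# Synthetic feedback-off current-time traces with telegraph blinks.
#
# Blinks are modelled as a two-state continuous-time Markov process: dwell
# times in the off (baseline) and on (blink) states are exponential with the
# configured means. The event sequence is simulated event-driven and then
# rasterized at the sampling rate, so dwell statistics are exact rather than
# approximated by per-sample Bernoulli switching. The in-blink current level
# is baseline + G * G0 * V_bias.

#' Configuration for synthetic blink traces
#'
#' @param baseline_current Baseline (set-point) current in nA.
#' @param blink_conductance Junction conductance in multiples of G0.
#' @param bias_voltage Bias in V.
#' @param mean_blink_lifetime Mean on-state dwell in s.
#' @param mean_interblink_time Mean off-state dwell in s (`Inf` for none).
#' @param sampling_rate Samples per second.
#' @param trace_duration Trace length in s.
#' @param noise_sd Additive Gaussian current noise s.d. in nA.
#' @param seed Integer seed (optional).
#' @return Object of class `blink_gen_config`.
#' @export
blink_gen_config <- function(baseline_current = 0.33,
                             blink_conductance = 4.3e-6,
                             bias_voltage = 0.8,
                             mean_blink_lifetime = 0.05,
                             mean_interblink_time = 0.25,
                             sampling_rate = 1e4,
                             trace_duration = 10,
                             noise_sd = 0.02,
                             seed = NULL) {
  if (mean_blink_lifetime <= 0 || mean_interblink_time <= 0 ||
      sampling_rate <= 0 || trace_duration <= 0)
    abort("rates, dwell means and duration must be positive", "smelt_config_error")
  if (blink_conductance < 0 || noise_sd < 0)
    abort("conductance and noise must be non-negative", "smelt_config_error")
  if (is.finite(mean_blink_lifetime) &&
      sampling_rate * mean_blink_lifetime < 10)
    warning("sampling_rate * mean_blink_lifetime < 10: blinks will be unresolvable")
  structure(list(baseline_current = baseline_current,
                 blink_conductance = blink_conductance,
                 bias_voltage = bias_voltage,
                 mean_blink_lifetime = mean_blink_lifetime,
                 mean_interblink_time = mean_interblink_time,
                 sampling_rate = sampling_rate,
                 trace_duration = trace_duration,
                 noise_sd = noise_sd, seed = seed),
            class = "blink_gen_config")
}

#' Blink amplitude implied by a conductance
#'
#' @param conductance Conductance in multiples of G0.
#' @param bias_voltage Bias in V.
#' @return Current step in nA (`G * G0 * V`).
#' @export
blink_amplitude <- function(conductance, bias_voltage) {
  conductance * conductance_quantum() * bias_voltage * 1e9
}

#' Generate a synthetic current-time trace with telegraph blinks
#'
#' @param config A [blink_gen_config()].
#' @return Object of class `current_trace`: `time` (s), `current` (nA),
#'   `bias_voltage`, `current_setpoint`, `sampling_rate`, and the ground
#'   truth in `events` (data frame: `onset`, `lifetime`, `amplitude`).
#' @export
gen_blink_trace <- function(config) {
  stopifnot(inherits(config, "blink_gen_config"))
  with_seed(config$seed, {
    fs <- config$sampling_rate
    n <- max(2L, round(config$trace_duration * fs))
    time <- (seq_len(n) - 1L) / fs
    amp <- blink_amplitude(config$blink_conductance, config$bias_voltage)

    onsets <- numeric(0); lifetimes <- numeric(0)
    if (is.finite(config$mean_interblink_time)) {
      t <- 0
      repeat {
        t_on <- t + rexp(1, 1 / config$mean_interblink_time)
        if (t_on >= config$trace_duration) break
        dwell <- rexp(1, 1 / config$mean_blink_lifetime)
        onsets <- c(onsets, t_on)
        lifetimes <- c(lifetimes, dwell)
        t <- t_on + dwell
      }
    }

    state <- logical(n)
    for (k in seq_along(onsets)) {
      i0 <- min(n, 1L + floor(onsets[k] * fs))
      i1 <- min(n, ceiling((onsets[k] + lifetimes[k]) * fs))
      if (i1 >= i0) state[i0:i1] <- TRUE
    }
    current <- config$baseline_current + amp * state
    if (config$noise_sd > 0) current <- current + rnorm(n, sd = config$noise_sd)

    structure(list(time = time, current = current,
                   bias_voltage = config$bias_voltage,
                   current_setpoint = config$baseline_current,
                   sampling_rate = fs,
                   events = data.frame(onset = onsets, lifetime = lifetimes,
                                       amplitude = rep(amp, length(onsets)))),
              class = "current_trace")
  })
}
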