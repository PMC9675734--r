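# Fixtures built in code: deterministic traces/curves used across test files.

# Noiseless telegraph trace with hand-placed blinks.
make_square_trace <- function(baseline = 0.33, amplitude = 0.267,
                              fs = 1e3, duration = 2,
                              on_windows = list(c(0.5, 0.6), c(1.2, 1.35))) {
  n <- duration * fs
  time <- (seq_len(n) - 1) / fs
  state <- rep(FALSE, n)
  for (w in on_windows) state[time >= w[1] & time < w[2]] <- TRUE
  structure(list(time = time, current = baseline + amplitude * state,
                 bias_voltage = 0.8, current_setpoint = baseline,
                 sampling_rate = fs,
                 events = data.frame(onset = vapply(on_windows, `[`, 1, 1),
                                     lifetime = vapply(on_windows, diff, 1),
                                     amplitude = amplitude)),
            class = "current_trace")
}

# Single sawtooth force curve with a rupture at (f_r, l_r), noiseless.
make_sawtooth_curve <- function(f_r = 55, l_r = 12, k_eff = 56,
                                velocity = 1, max_sep = 30, n = 1024) {
  sep <- seq(0, max_sep, length.out = n)
  s0 <- l_r - f_r / k_eff
  force <- numeric(n)
  ramp <- sep > s0 & sep <= l_r
  force[ramp] <- -(sep[ramp] - s0) * k_eff
  structure(list(separation = sep, force = force,
                 pulling_velocity = velocity, cantilever_stiffness = k_eff,
                 metadata = list(has_event = TRUE, f_rupture = f_r,
                                 l_rupture = l_r)),
            class = "force_curve")
}
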