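# Blink detection and conductance analysis of feedback-off current traces.
#
# Detection uses a two-threshold hysteresis scheme on the baseline-subtracted
# current: an excursion must exceed baseline + k*sigma to count and extends
# over all contiguous samples above baseline + (k/2)*sigma. Noise sigma is
# estimated by the median absolute deviation of below-threshold samples, so
# it is robust to the blinks themselves.

#' Rolling-median baseline of a current trace
#'
#' Robust to telegraph excursions occupying less than half of any window and
#' tracks slow drift.
#'
#' @param trace A `current_trace`.
#' @param window Window length in seconds (>= 10 samples).
#' @return Numeric baseline series (nA), same length as the trace.
#' @export
estimate_baseline <- function(trace, window = 0.5) {
  fs <- trace$sampling_rate
  k <- round(window * fs)
  n <- length(trace$current)
  if (k < 10L)
    abort("baseline window must span at least 10 samples", "smelt_invalid_window")
  if (k > n)
    abort("baseline window longer than the trace", "smelt_invalid_window")
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  as.numeric(stats::runmed(trace$current, k, endrule = "median"))
}

#' Detect current blinks by hysteresis thresholding
#'
#' @param trace A `current_trace`.
#' @param baseline Baseline series from [estimate_baseline()] (or a scalar).
#' @param threshold_sigmas Entry threshold k in noise s.d. units; the exit
#'   threshold is k/2.
#' @param min_duration Minimum event duration in s (default 3 samples).
#' @return Object of class `blink_events`: data frame with `onset` (s),
#'   `lifetime` (s), `i_blink` (baseline-subtracted plateau, nA),
#'   `i_baseline` (nA), `conductance` (multiples of G0), `start`, `end`
#'   (sample indices). The per-sample baseline-subtracted currents of each
#'   event are kept in attribute `"samples"`; noise sigma in `"sigma"`.
#' @export
detect_blinks <- function(trace, baseline = estimate_baseline(trace),
                          threshold_sigmas = 5,
                          min_duration = 3 / trace$sampling_rate) {
  resid <- trace$current - baseline
  sigma0 <- mad(resid)
  below <- resid < threshold_sigmas / 2 * sigma0
  sigma <- if (any(below)) mad(resid[below]) else sigma0

  enter <- threshold_sigmas * sigma
  exit <- enter / 2
  above_exit <- resid > exit
  r <- rle(above_exit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- max(1L, round(min_duration * trace$sampling_rate))

  rows <- list(); samples <- list()
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (e - s + 1L < min_len) next
    if (!any(resid[s:e] > enter)) next
    seg <- resid[s:e]
    rows[[length(rows) + 1L]] <- data.frame(
      onset = trace$time[s],
      lifetime = (e - s + 1L) / trace$sampling_rate,
      i_blink = median(seg),
      i_baseline = median(baseline[s:e]),
      conductance = median(seg) * 1e-9 / trace$bias_voltage / conductance_quantum(),
      start = s, end = e)
    samples[[length(samples) + 1L]] <- seg
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset = numeric(0), lifetime = numeric(0), i_blink = numeric(0),
               i_baseline = numeric(0), conductance = numeric(0),
               start = integer(0), end = integer(0))
  rownames(ev) <- NULL
  structure(ev, samples = samples, sigma = sigma,
            bias_voltage = trace$bias_voltage,
            current_setpoint = trace$current_setpoint,
            sampling_rate = trace$sampling_rate,
            class = c("blink_events", "data.frame"))
}

#' Build a normalized 2D blink map
#'
#' Re-times every detected event to a common origin (blink onset = 0) and
#' accumulates the in-blink, baseline-subtracted samples in a 2D histogram
#' over (time, current), normalized so the maximum bin equals 100.
#'
#' @param events A `blink_events` object (with its `"samples"` attribute).
#' @param time_bins,current_bins Number of bins along each axis.
#' @return Object of class `blink_map`: `time_axis`, `current_axis` (bin
#'   midpoints), `counts` (matrix, max 100), `n_events`.
#' @export
build_blink_map <- function(events, time_bins = 50, current_bins = 50) {
  samples <- attr(events, "samples")
  fs <- attr(events, "sampling_rate")
  if (nrow(events) == 0L)
    abort("no events to map", "smelt_empty_map")
  tt <- unlist(lapply(samples, function(s) (seq_along(s) - 1L) / fs))
  ii <- unlist(samples)
  tb <- seq(0, max(tt) + 1 / fs, length.out = time_bins + 1L)
  rng <- range(ii)
  if (diff(rng) == 0) rng <- rng + c(-1, 1) * max(abs(rng), 1e-6) * 0.05
  ib <- seq(rng[1], rng[2], length.out = current_bins + 1L)
  ti <- pmin(findInterval(tt, tb, rightmost.closed = TRUE), time_bins)
  ci <- pmin(findInterval(ii, ib, rightmost.closed = TRUE), current_bins)
  counts <- matrix(0, nrow = time_bins, ncol = current_bins)
  for (k in seq_along(ti)) counts[ti[k], ci[k]] <- counts[ti[k], ci[k]] + 1
  counts <- counts / max(counts) * 100
  structure(list(time_axis = (tb[-1] + tb[-length(tb)]) / 2,
                 current_axis = (ib[-1] + ib[-length(ib)]) / 2,
                 counts = counts, n_events = nrow(events)),
            class = "blink_map")
}

#' Conductance histogram and main-peak Gaussian fit
#'
#' By default conductance values are accumulated per sample (every in-blink
#' sample contributes `I/(V * G0)`), matching 2D-map statistics whose counts
#' far exceed the event count; per-event values (one median conductance per
#' blink) are available via `per_sample = FALSE`.
#'
#' @param events A `blink_events` object (>= 20 events).
#' @param bias Bias voltage in V (default: the value stored at detection).
#' @param per_sample Logical; see above.
#' @return List with `center` and `width` of the main conductance peak
#'   (multiples of G0), `values`, `n`, and the `histogram`.
#' @export
conductance_profile <- function(events, bias = attr(events, "bias_voltage"),
                                per_sample = TRUE) {
  if (is.null(bias) || !is.finite(bias) || bias == 0)
    abort("bias voltage must be non-zero", "smelt_invalid_bias")
  if (nrow(events) < 20L)
    abort("need at least 20 events", "smelt_insufficient_data")
  g0 <- conductance_quantum()
  values <- if (per_sample) {
    unlist(attr(events, "samples")) * 1e-9 / bias / g0
  } else {
    events$i_blink * 1e-9 / bias / g0
  }
  pk <- fit_gaussian_peak(values)
  list(center = pk$center, width = pk$width, values = values,
       n = length(values), histogram = pk$histogram)
}

#' Blink current versus its local baseline
#'
#' @param events A `blink_events` object (>= 1 event).
#' @param setpoint Current set point in nA (default: stored at detection).
#' @return List with the paired `table` (`i_baseline`, `i_blink`), their
#'   means and s.d., the `setpoint`, and `fraction_below_setpoint` -- the
#'   fraction of events whose baseline lies below the set point, i.e. blinks
#'   occurring at distances beyond the set-point gap.
#' @export
blink_vs_baseline <- function(events, setpoint = attr(events, "current_setpoint")) {
  if (nrow(events) == 0L)
    abort("no events", "smelt_insufficient_data")
  tab <- data.frame(i_baseline = events$i_baseline, i_blink = events$i_blink)
  list(table = tab,
       mean_baseline = mean(tab$i_baseline), sd_baseline = sd(tab$i_baseline),
       mean_blink = mean(tab$i_blink), sd_blink = sd(tab$i_blink),
       setpoint = setpoint,
       fraction_below_setpoint = mean(tab$i_baseline < setpoint))
}
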