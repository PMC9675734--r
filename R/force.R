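# Rupture-event detection and Bell-Evans dynamic force spectroscopy.
#
# Convention: adhesive (pulling) forces are negative in raw retraction
# curves; rupture forces F_r are reported positive. The zero-force baseline
# is taken from the far-retraction tail, after the last possible unbinding.

#' Detect unbinding events in a force-separation retraction curve
#'
#' Ruptures are negative-force excursions (below baseline - 3 sigma) that
#' terminate in a discontinuous jump back to baseline: within at most 3
#' samples the force must return to within 3 sigma of the baseline with a
#' jump exceeding 3 sigma. The pre-rupture force is estimated by a local
#' linear fit over up to 20 samples before the jump, which also provides the
#' loading rate `r = |dF/ds| * v`.
#'
#' @param curve A `force_curve`.
#' @param tail_fraction Fraction of the trace (far end) used for the baseline
#'   and noise estimate.
#' @param min_run Minimum number of consecutive below-threshold samples an
#'   excursion must contain; single-sample noise spikes below -3 sigma are
#'   otherwise indistinguishable from shallow ruptures.
#' @return Object of class `rupture_events`: data frame with `f_rupture`
#'   (pN), `l_rupture` (nm), `loading_rate` (pN/s), `index`.
#' @export
detect_ruptures <- function(curve, tail_fraction = 0.1, min_run = 3L) {
  force <- curve$force
  sep <- curve$separation
  n <- length(force)
  tail_idx <- seq.int(max(1L, floor((1 - tail_fraction) * n)), n)
  if (length(tail_idx) < 10L)
    abort("no baseline tail after retraction", "smelt_baseline_undefined")
  baseline <- median(force[tail_idx])
  sigma <- mad(force[tail_idx])
  thr <- 3 * sigma
  v_nm <- curve$pulling_velocity * 1000

  below <- force < baseline - thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    if (e - s + 1L < min_run) next
    # discontinuous return to baseline within <= 3 samples?
    ret <- FALSE
    for (k in 1:3) {
      if (e + k > n) break
      jump <- force[e + k] - force[e]
      near <- abs(force[e + k] - baseline) <= max(thr, 1e-9)
      if (near && jump > max(thr, 1e-9)) { ret <- TRUE; break }
    }
    if (!ret) next
    w <- seq.int(max(s, e - 19L), e)
    if (length(w) >= 3L) {
      loc <- lm(force[w] ~ sep[w])
      f_pre <- coef(loc)[[1]] + coef(loc)[[2]] * sep[e]
      slope <- coef(loc)[[2]]
    } else {
      f_pre <- force[e]
      slope <- -curve$cantilever_stiffness
    }
    rows[[length(rows) + 1L]] <- data.frame(
      f_rupture = baseline - f_pre,
      l_rupture = sep[e],
      loading_rate = abs(slope) * v_nm,
      index = e)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(f_rupture = numeric(0), l_rupture = numeric(0),
               loading_rate = numeric(0), index = integer(0))
  ev <- ev[ev$f_rupture > 0, , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, baseline = baseline, sigma = sigma,
            class = c("rupture_events", "data.frame"))
}

#' Detect ruptures across an ensemble of curves
#'
#' @param curves List of `force_curve` objects.
#' @param ... Passed to [detect_ruptures()].
#' @return Data frame of all events with a `curve` column.
#' @export
detect_ruptures_ensemble <- function(curves, ...) {
  rows <- lapply(seq_along(curves), function(i) {
    ev <- tryCatch(detect_ruptures(curves[[i]], ...),
                   smelt_error = function(e) NULL)
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    cbind(curve = i, as.data.frame(ev))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(curve = integer(0), f_rupture = numeric(0),
                      l_rupture = numeric(0), loading_rate = numeric(0),
                      index = integer(0))
  out
}

#' Rupture-force distribution at one pulling velocity
#'
#' Reports both the Gaussian center of the main histogram peak and the raw
#' arithmetic mean: skewed distributions make the two differ (e.g. a 55 pN
#' center with a 75 pN mean), so both are kept.
#'
#' @param f_rupture Rupture forces in pN (>= 30 events).
#' @return List with `center`, `width` (Gaussian, pN), `mean` (pN), `n`,
#'   `histogram`.
#' @export
force_distribution <- function(f_rupture) {
  f_rupture <- f_rupture[is.finite(f_rupture)]
  if (length(f_rupture) < 30L)
    abort("need at least 30 rupture events", "smelt_insufficient_data")
  pk <- fit_gaussian_peak(f_rupture)
  list(center = pk$center, width = pk$width, mean = mean(f_rupture),
       n = length(f_rupture), histogram = pk$histogram)
}

#' Most probable rupture force under the Bell-Evans model
#'
#' `F* = (k_BT/x_u) ln(x_u r / (k0_u k_BT))`, clamped at 0 when the
#' logarithm's argument is at or below 1 (spontaneous dissociation outruns
#' loading).
#'
#' @param k0_u Zero-force unbinding rate in 1/s.
#' @param x_u Distance to the barrier in nm.
#' @param loading_rate Loading rate(s) in pN/s (vectorized).
#' @param temperature Temperature in K.
#' @return Most probable force(s) in pN.
#' @export
most_probable_force <- function(k0_u, x_u, loading_rate, temperature = 298) {
  if (k0_u <= 0 || x_u <= 0 || any(loading_rate <= 0) || temperature <= 0)
    abort("all Bell-Evans arguments must be positive", "smelt_domain_error")
  kbt <- thermal_energy(temperature)
  arg <- x_u * loading_rate / (k0_u * kbt)
  ifelse(arg <= 1, 0, (kbt / x_u) * log(arg))
}

#' Bell-Evans fit of most-probable force versus loading rate
#'
#' Fits `F* = a + b ln(r)` and inverts it exactly: `x_u = k_BT / b` and
#' `k0_u = (x_u / k_BT) exp(-a/b)`, so that feeding forces generated by
#' [most_probable_force()] recovers the parameters to machine precision.
#' A non-positive or insignificant slope indicates force-independent
#' (near-equilibrium) unbinding and leaves `k0_u`/`x_u` undefined.
#'
#' @param loading_rate Loading rates in pN/s (>= 3 distinct values).
#' @param force Most probable forces in pN.
#' @param temperature Temperature in K.
#' @param alpha Significance level for the slope (regime call).
#' @return Object of class `bell_evans_fit`: `k0_u`, `x_u`, `slope`,
#'   `intercept`, `slope_p_value`, `temperature`, `regime`, `n_rates`.
#' @export
bell_evans_fit <- function(loading_rate, force, temperature = 298, alpha = 0.05) {
  if (length(unique(loading_rate)) < 3L)
    abort("need at least 3 distinct loading rates", "smelt_insufficient_data")
  if (length(loading_rate) != length(force))
    abort("loading_rate and force lengths differ", "smelt_config_error")
  kbt <- thermal_energy(temperature)
  lr <- log(loading_rate)
  fit <- lm(force ~ lr)
  a <- coef(fit)[[1]]; b <- coef(fit)[[2]]
  sm <- suppressWarnings(summary(fit))$coefficients  # exact data: zero residuals
  pval <- if (nrow(sm) >= 2L && is.finite(sm[2, 4])) sm[2, 4] else 0
  if (!is.finite(sm[2, 2]) || sm[2, 2] == 0) pval <- 0
  if (b <= 0) {
    out <- list(k0_u = NA_real_, x_u = NA_real_, slope = b, intercept = a,
                slope_p_value = pval, temperature = temperature,
                regime = "near_equilibrium", n_rates = length(unique(loading_rate)))
  } else {
    x_u <- kbt / b
    k0_u <- (x_u / kbt) * exp(-a / b)
    out <- list(k0_u = k0_u, x_u = x_u, slope = b, intercept = a,
                slope_p_value = pval, temperature = temperature,
                regime = if (pval < alpha) "kinetic" else "near_equilibrium",
                n_rates = length(unique(loading_rate)))
  }
  structure(out, class = "bell_evans_fit")
}

#' Classify the unbinding regime of a Bell-Evans fit
#'
#' Kinetic (non-equilibrium bond rupture) if the force-vs-ln(rate) slope is
#' positive and significant at `alpha`; otherwise near-equilibrium, where
#' rebinding outpaces pulling and the rupture force is rate independent.
#'
#' @param fit A `bell_evans_fit`.
#' @param alpha Significance level.
#' @return `"kinetic"` or `"near_equilibrium"`.
#' @export
classify_regime <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "bell_evans_fit"))
  if (fit$n_rates < 3L)
    abort("need at least 3 distinct loading rates", "smelt_insufficient_data")
  if (fit$slope > 0 && fit$slope_p_value < alpha) "kinetic" else "near_equilibrium"
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf("Bell-Evans fit (%s regime): slope %.3g pN per ln(pN/s)\n",
              x$regime, x$slope))
  if (is.finite(x$k0_u %||% NA))
    cat(sprintf("  k0_u = %.4g 1/s, x_u = %.4g nm\n", x$k0_u, x$x_u))
  invisible(x)
}
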