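# Distance-decay analysis of tunneling I-z retraction curves.
#
# The decay factor beta (nm^-1) quantifies how fast the tunneling current
# falls with probe-sample distance. Curves decay exponentially from the set
# point down to a distance-independent faradaic leakage floor, so the fit is
# restricted to the exponential window above that floor.

#' Fit the exponential decay region of an I-z curve
#'
#' Estimates the leakage floor (median of the last 10% of samples unless a
#' hint is supplied), selects the contiguous window of points with current
#' above 3x the floor -- excluding the first two points after feedback-off,
#' which carry the switching transient -- and fits
#' `I(z) = A exp(-beta z) + I_leak` by nonlinear least squares with the
#' leakage free. If the nonlinear fit fails it falls back to log-linear
#' regression of `I - I_leak`.
#'
#' @param curve An `iz_curve` (or a list with numeric `z` and `current`).
#' @param leakage_hint Leakage floor in nA, or `NULL` to estimate it.
#' @param r2_flag Curves with window r^2 below this are flagged (not dropped).
#' @return Object of class `decay_fit`: `beta` (nm^-1), `amplitude`,
#'   `leakage` (nA), `fit_window` (nm), `r_squared`, `n_points_used`,
#'   `flagged`.
#' @export
fit_decay <- function(curve, leakage_hint = NULL, r2_flag = 0.8) {
  z <- curve$z
  current <- curve$current
  if (length(z) != length(current) || length(z) < 8L)
    abort("curve needs matching z/current with >= 8 points", "smelt_config_error")
  if (!all(is.finite(current)))
    abort("currents must be finite", "smelt_config_error")

  n <- length(current)
  tail_idx <- seq.int(max(1L, floor(0.9 * n)), n)
  leak <- leakage_hint %||% median(current[tail_idx])

  ok <- which(current > 3 * leak)
  ok <- ok[ok > 2L]  # drop the feedback-off transient
  if (length(ok) == 0L)
    abort("no region above 3x the leakage floor", "smelt_no_decay_region")
  # leading contiguous run (the decay leaves the floor only once)
  run_end <- which(diff(ok) > 1L)
  win <- if (length(run_end)) ok[seq_len(run_end[1])] else ok
  if (length(win) < 8L)
    abort("fewer than 8 points above the leakage floor", "smelt_no_decay_region")

  zw <- z[win]; iw <- current[win]
  eps <- max(1e-12, 1e-6 * max(iw))
  ll <- lm(log(pmax(iw - leak, eps)) ~ zw)
  beta0 <- max(-coef(ll)[[2]], 1e-3)
  a0 <- max(exp(coef(ll)[[1]]), eps)

  fit <- tryCatch(
    minpack.lm::nlsLM(iw ~ A * exp(-beta * zw) + leakf,
                      start = list(A = a0, beta = beta0, leakf = leak),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    beta <- unname(cf["beta"]); A <- unname(cf["A"]); leak_fit <- unname(cf["leakf"])
    pred <- A * exp(-beta * zw) + leak_fit
  } else {
    beta <- beta0; A <- a0; leak_fit <- leak
    pred <- A * exp(-beta * zw) + leak_fit
  }
  if (!is.finite(beta) || beta <= 0)
    abort("decay fit did not converge to a positive beta", "smelt_fit_failure")

  ss_res <- sum((iw - pred)^2)
  ss_tot <- sum((iw - mean(iw))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1

  structure(list(beta = beta, amplitude = A, leakage = leak_fit,
                 fit_window = c(z_start = zw[1], z_end = zw[length(zw)]),
                 r_squared = r2, n_points_used = length(win),
                 flagged = r2 < r2_flag),
            class = "decay_fit")
}

#' Fit decay factors for a whole ensemble
#'
#' @param curves List of `iz_curve` objects.
#' @param ... Passed to [fit_decay()].
#' @return Data frame with one row per curve: `beta`, `r_squared`, `flagged`,
#'   `gate`, `bias`, and the generator's `beta_true`/`component` when present.
#' @export
fit_decay_ensemble <- function(curves, ...) {
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    f <- tryCatch(fit_decay(cv, ...), smelt_error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(curve = i, beta = f$beta, r_squared = f$r_squared,
               flagged = f$flagged,
               gate = cv$gate %||% NA_real_, bias = cv$bias %||% NA_real_,
               beta_true = cv$metadata$beta_true %||% NA_real_,
               component = cv$metadata$component %||% NA_integer_)
  })
  do.call(rbind, rows)
}

#' Model a population of decay factors as a 1- or 2-component Gaussian mixture
#'
#' Fits one- and two-component Gaussian mixtures to the raw beta values and
#' selects between them by BIC, which captures the unimodal/bimodal contrast
#' between the wild-type-like and phosphomimetic-like ensembles.
#'
#' @param betas Numeric vector of decay factors (nm^-1), length >= 20.
#' @return Object of class `beta_population`: `n_components`, `centers`
#'   (ascending), `widths` (s.d.), `weights`, `bic_per_model` (named, larger
#'   is better under mclust's convention).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_beta_population <- function(betas) {
  betas <- betas[is.finite(betas)]
  if (length(betas) < 20L)
    abort("need at least 20 beta values", "smelt_insufficient_data")
  if (sd(betas) == 0) {
    return(structure(list(n_components = 1L, centers = betas[1], widths = 0,
                          weights = 1, bic_per_model = c(`1` = NA_real_, `2` = NA_real_)),
                     class = "beta_population"))
  }
  bic <- mclustBIC(betas, G = 1:2, verbose = FALSE)
  mod <- Mclust(betas, x = bic, verbose = FALSE)
  par <- mod$parameters
  centers <- as.numeric(par$mean)
  vars <- par$variance$sigmasq
  if (length(vars) == 1L) vars <- rep(vars, mod$G)
  widths <- sqrt(as.numeric(vars))
  weights <- as.numeric(par$pro)
  ord <- order(centers)
  bic_best <- apply(bic, 1, max, na.rm = TRUE)
  structure(list(n_components = mod$G, centers = centers[ord],
                 widths = widths[ord], weights = weights[ord],
                 bic_per_model = bic_best),
            class = "beta_population")
}

#' @export
print.beta_population <- function(x, ...) {
  cat(sprintf("beta population: %d component(s)\n", x$n_components))
  for (i in seq_len(x$n_components))
    cat(sprintf("  component %d: %.3g +/- %.2g nm^-1 (weight %.2f)\n",
                i, x$centers[i], x$widths[i], x$weights[i]))
  invisible(x)
}

#' Aggregate decay factors by electrochemical gate potential
#'
#' @param gate Gate potential (V) per curve.
#' @param beta Decay factor (nm^-1) per curve.
#' @return Data frame sorted by gate with `gate`, `mean_beta`, `sd_beta`, `n`;
#'   the gate of minimum mean beta is in attribute `"gate_min"`. Groups with a
#'   single curve are dropped.
#' @export
beta_vs_gate <- function(gate, beta) {
  keep <- is.finite(gate) & is.finite(beta)
  gate <- gate[keep]; beta <- beta[keep]
  if (length(gate) == 0L)
    abort("no (gate, beta) pairs supplied", "smelt_insufficient_data")
  sp <- split(beta, gate)
  sp <- sp[vapply(sp, length, 1L) >= 2L]
  if (length(sp) == 0L)
    abort("every gate group has fewer than 2 curves", "smelt_insufficient_data")
  out <- data.frame(gate = as.numeric(names(sp)),
                    mean_beta = vapply(sp, mean, 1),
                    sd_beta = vapply(sp, sd, 1),
                    n = vapply(sp, length, 1L))
  out <- out[order(out$gate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gate_min") <- out$gate[which.min(out$mean_beta)]
  out
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t-test with pooled variance, the convention whose
#' degrees of freedom are `n_a + n_b - 2`. Degenerate zero-variance input
#' with equal means returns t = 0 by convention.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
compare_groups <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    abort("each group needs at least 2 values", "smelt_insufficient_data")
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  if (se == 0) {
    tval <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
  } else {
    tval <- (mean(a) - mean(b)) / se
  }
  list(t = tval, df = df, p_value = 2 * pt(-abs(tval), df))
}
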