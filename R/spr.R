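# Global 1:1 Langmuir fitting of SPR sensograms.
#
# The closed-form one-site model is fitted directly (no ODE integration):
# kon, koff and rmax are shared across all curves by default, matching a
# single immobilized surface probed at several analyte concentrations.

#' Off-rate from the dissociation phase
#'
#' Log-linear regression of the dissociation decay; used to initialize the
#' global fit.
#'
#' @param sensogram A `sensogram`.
#' @return List with `koff` (1/s) and `flagged` (TRUE when the decay is
#'   indistinguishable from flat).
#' @export
koff_from_dissociation <- function(sensogram) {
  idx <- which(sensogram$time > sensogram$association_end)
  t <- sensogram$time[idx] - sensogram$association_end
  r <- sensogram$response[idx]
  pos <- which(r <= 0)
  if (length(pos)) {
    keep <- seq_len(pos[1] - 1L)
    t <- t[keep]; r <- r[keep]
  }
  if (length(r) < 10L)
    abort("dissociation phase has fewer than 10 positive points",
          "smelt_init_failure")
  fit <- lm(log(r) ~ t)
  koff <- -coef(fit)[[2]]
  list(koff = koff, flagged = koff <= 0)
}

#' Global 1:1 kinetic fit of SPR sensograms
#'
#' Simultaneous least-squares fit of the closed-form 1:1 Langmuir model to
#' one or more sensograms, sharing `kon`, `koff` and (by default) `rmax`.
#' Parameters are optimized on the log scale; initialization comes from the
#' dissociation slope ([koff_from_dissociation()]) and a per-curve observed
#' rate `k_obs = kon C + koff` regression.
#'
#' @param sensograms A `sensogram_set` or list of `sensogram` objects.
#' @param shared_rmax Share rmax across curves (default TRUE; per-curve rmax
#'   otherwise).
#' @return Object of class `binding_kinetics`: `kon` (1/(M s)), `koff`
#'   (1/s), `kd` (M, recomputed as koff/kon), `rmax` (RU), `standard_errors`,
#'   `r_squared`.
#' @export
fit_global_1to1 <- function(sensograms, shared_rmax = TRUE) {
  sgs <- unclass(sensograms)
  if (length(sgs) < 1L) abort("no sensograms", "smelt_config_error")
  concs <- vapply(sgs, function(s) s$analyte_concentration, 1)
  if (length(sgs) > 1L && anyDuplicated(signif(concs, 10)))
    abort("concentrations must be distinct for a multi-curve fit",
          "smelt_config_error")

  # --- initialization ---------------------------------------------------
  koff0 <- median(vapply(sgs, function(s) koff_from_dissociation(s)$koff, 1))
  koff0 <- max(koff0, 1e-6)
  kobs0 <- vapply(seq_along(sgs), function(i) {
    s <- sgs[[i]]
    idx <- which(s$time <= s$association_end & s$time > 0)
    t <- s$time[idx]; r <- s$response[idx]
    req0 <- max(r)
    f <- tryCatch(
      minpack.lm::nlsLM(r ~ req * (1 - exp(-kobs * t)),
                        start = list(req = req0, kobs = 3 / max(t))),
      error = function(e) NULL)
    if (is.null(f)) 3 / max(t) else coef(f)[["kobs"]]
  }, 1)
  kon0 <- max(median((kobs0 - koff0) / concs), 1)
  req_obs <- vapply(sgs, function(s) max(s$response), 1)
  rmax0 <- max(req_obs * (concs + koff0 / kon0) / concs)

  n_rmax <- if (shared_rmax) 1L else length(sgs)
  par0 <- c(log(kon0), log(koff0), rep(log(rmax0), n_rmax))

  resid_fun <- function(p) {
    kon <- exp(p[1]); koff <- exp(p[2])
    rmax <- exp(p[2 + seq_len(n_rmax)])
    unlist(lapply(seq_along(sgs), function(i) {
      s <- sgs[[i]]
      rm_i <- if (shared_rmax) rmax[1] else rmax[i]
      pred <- spr_model_response(s$time, s$association_end,
                                 s$analyte_concentration, kon, koff, rm_i)
      s$response - pred
    }))
  }

  opt <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (opt$info < 1 || opt$info > 4)
    abort(sprintf("global 1:1 fit did not converge (info = %d; init kon=%.3g, koff=%.3g)",
                  opt$info, kon0, koff0), "smelt_fit_failure")
  p <- opt$par
  kon <- exp(p[1]); koff <- exp(p[2])
  rmax <- exp(p[2 + seq_len(n_rmax)])

  # delta-method standard errors from the fit covariance (log scale)
  se_log <- rep(NA_real_, length(p))
  cv <- tryCatch(vcov(opt), error = function(e) NULL)
  if (!is.null(cv)) se_log <- sqrt(pmax(diag(cv), 0))
  se <- c(kon = se_log[1] * kon, koff = se_log[2] * koff,
          rmax = se_log[3] * rmax[1])

  obs <- unlist(lapply(sgs, function(s) s$response))
  ss_res <- sum(resid_fun(p)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1

  structure(list(kon = kon, koff = koff, kd = koff / kon,
                 rmax = if (shared_rmax) rmax[1] else rmax,
                 standard_errors = se, r_squared = r2,
                 n_curves = length(sgs), concentrations = concs),
            class = "binding_kinetics")
}

#' Equilibrium dissociation constant from fitted kinetics
#'
#' @param kinetics A `binding_kinetics` (or any list with `kon`, `koff`).
#' @return K_D = koff/kon in M.
#' @export
compute_kd <- function(kinetics) {
  if (is.null(kinetics$kon) || kinetics$kon <= 0)
    abort("kon must be positive", "smelt_domain_error")
  kinetics$koff / kinetics$kon
}

#' @export
print.binding_kinetics <- function(x, ...) {
  cat(sprintf("1:1 binding kinetics (%d curve(s), R^2 = %.4f)\n",
              x$n_curves, x$r_squared))
  cat(sprintf("  kon  = %.4g 1/(M s)\n  koff = %.4g 1/s\n  K_D  = %.4g M\n",
              x$kon, x$koff, x$kd))
  invisible(x)
}
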