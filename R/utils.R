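# Shared helpers: classed error conditions and the Gaussian peak fitter used
# by the beta, conductance and rupture-force histograms.

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "smelt_error", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Truncated-normal draws by resampling; adequate away from heavy truncation.
rnorm_pos <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
  }
  out[out <= lower] <- lower + sd * 1e-3
  out
}

#' Fit a Gaussian to the main peak of a histogram
#'
#' Histograms of single-molecule observables (decay factors, conductances,
#' rupture forces) are routinely summarised by a Gaussian fitted around the
#' highest peak, which is robust to skew and secondary populations. Bins are
#' Freedman--Diaconis by default; the fit uses the contiguous run of bins
#' around the peak with counts above 20% of the peak count.
#'
#' @param x Numeric values.
#' @param breaks Passed to [graphics::hist()] (default `"FD"`).
#' @return List with `center`, `width` (Gaussian s.d.), `n`, and the
#'   `histogram` object.
#' @export
fit_gaussian_peak <- function(x, breaks = "FD") {
  x <- x[is.finite(x)]
  if (length(x) < 2L) abort("need at least 2 finite values", "smelt_insufficient_data")
  if (diff(range(x)) == 0) {
    return(list(center = x[1], width = 0, n = length(x), histogram = NULL))
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  peak <- which.max(counts)
  keep <- counts >= 0.2 * counts[peak]
  lo <- peak; while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- peak; while (hi < length(keep) && keep[hi + 1L]) hi <- hi + 1L
  sel <- lo:hi
  if (length(sel) < 4L) {
    sel <- max(1L, peak - 3L):min(length(mids), peak + 3L)
  }
  w <- counts[sel]
  mu0 <- sum(mids[sel] * w) / sum(w)
  s0 <- sqrt(sum(w * (mids[sel] - mu0)^2) / sum(w))
  binw <- diff(h$breaks[1:2])
  if (!is.finite(s0) || s0 == 0) s0 <- binw
  df <- data.frame(m = mids[sel], cnt = counts[sel])
  fit <- tryCatch(
    minpack.lm::nlsLM(cnt ~ A * exp(-(m - mu)^2 / (2 * s^2)),
                      data = df,
                      start = list(A = counts[peak], mu = mu0, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    center <- mu0; width <- s0
  } else {
    cf <- coef(fit)
    center <- unname(cf["mu"]); width <- abs(unname(cf["s"]))
  }
  list(center = center, width = max(width, binw / 2), n = length(x), histogram = h)
}
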