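# Synthetic tunneling current-distance (I-z) retraction curves.
#
# The generative model is the one the decay analysis assumes:
#   I(z) = I_sp * exp(-beta * z) + I_leak
# with beta drawn per curve from a (possibly multi-component) Gaussian
# mixture, and multiplicative Gaussian measurement noise. Defaults follow the
# experimental protocol: 0.4 nA set point, 15 nm retraction span, 1024 points,
# faradaic leakage of a few pA.

#' Configuration for synthetic I-z retraction curves
#'
#' @param beta_components Data frame with columns `center` (nm^-1), `sd`
#'   (nm^-1, per-curve spread of the decay factor; 0 for a fixed value) and
#'   `weight` (fractions summing to 1). One row per population.
#' @param current_setpoint Initial current set point in nA.
#' @param leakage_current Distance-independent faradaic leakage floor in nA.
#' @param retraction_length Retraction span in nm.
#' @param points_per_curve Samples per curve.
#' @param noise_fraction Multiplicative relative s.d. of the current noise.
#' @param n_curves Number of curves to generate.
#' @param sample_potential,probe_potential Electrode potentials in V vs the
#'   reference; the bias is their difference and the EC gate is minus the
#'   sample potential.
#' @param seed Integer seed (optional).
#' @return An object of class `iz_gen_config`.
#' @export
iz_gen_config <- function(beta_components = data.frame(center = 1.3, sd = 0, weight = 1),
                          current_setpoint = 0.4,
                          leakage_current = 0.002,
                          retraction_length = 15,
                          points_per_curve = 1024,
                          noise_fraction = 0.05,
                          n_curves = 100,
                          sample_potential = -0.2,
                          probe_potential = 0.6,
                          seed = NULL) {
  bc <- as.data.frame(beta_components)
  if (!all(c("center", "weight") %in% names(bc)))
    abort("beta_components needs 'center' and 'weight' columns", "smelt_config_error")
  if (is.null(bc$sd)) bc$sd <- 0
  if (abs(sum(bc$weight) - 1) > 1e-8)
    abort("beta component weights must sum to 1", "smelt_config_error")
  if (any(bc$center <= 0))
    abort("decay constants must be positive", "smelt_config_error")
  if (any(bc$sd < 0))
    abort("component sd must be non-negative", "smelt_config_error")
  if (leakage_current >= current_setpoint)
    abort("leakage current must be below the set point", "smelt_config_error")
  if (retraction_length <= 0)
    abort("retraction length must be positive", "smelt_config_error")
  if (points_per_curve < 2)
    abort("need at least 2 points per curve", "smelt_config_error")
  if (noise_fraction < 0 || n_curves < 1)
    abort("invalid noise fraction or curve count", "smelt_config_error")
  structure(list(beta_components = bc, current_setpoint = current_setpoint,
                 leakage_current = leakage_current,
                 retraction_length = retraction_length,
                 points_per_curve = points_per_curve,
                 noise_fraction = noise_fraction, n_curves = n_curves,
                 sample_potential = sample_potential,
                 probe_potential = probe_potential, seed = seed),
            class = "iz_gen_config")
}

new_iz_curve <- function(z, current, sample_potential, probe_potential, metadata = list()) {
  structure(list(z = z, current = current,
                 sample_potential = sample_potential,
                 probe_potential = probe_potential,
                 bias = probe_potential - sample_potential,
                 gate = -sample_potential,
                 metadata = metadata),
            class = "iz_curve")
}

#' Generate an ensemble of synthetic I-z retraction curves
#'
#' Each curve follows `I(z) = I_sp * exp(-beta z) + I_leak` with `beta` drawn
#' from the configured component mixture and multiplicative Gaussian noise.
#' The ground-truth decay factor and component index are stored in each
#' curve's metadata.
#'
#' @param config An [iz_gen_config()].
#' @return List of `iz_curve` objects (class `iz_ensemble`).
#' @export
gen_iz_ensemble <- function(config) {
  stopifnot(inherits(config, "iz_gen_config"))
  with_seed(config$seed, {
    bc <- config$beta_components
    z <- seq(0, config$retraction_length, length.out = config$points_per_curve)
    curves <- vector("list", config$n_curves)
    comp <- sample.int(nrow(bc), config$n_curves, replace = TRUE, prob = bc$weight)
    for (i in seq_len(config$n_curves)) {
      k <- comp[i]
      beta <- rnorm_pos(1, bc$center[k], bc$sd[k], lower = 0.05)
      model <- config$current_setpoint * exp(-beta * z) + config$leakage_current
      current <- model * (1 + config$noise_fraction * rnorm(length(z)))
      curves[[i]] <- new_iz_curve(
        z, current, config$sample_potential, config$probe_potential,
        metadata = list(beta_true = beta, component = k,
                        current_setpoint = config$current_setpoint,
                        leakage_current = config$leakage_current))
    }
    structure(curves, class = "iz_ensemble")
  })
}

#' @export
print.iz_curve <- function(x, ...) {
  cat(sprintf("I-z retraction curve: %d points over %.2f nm, bias %.3g V, gate %.3g V\n",
              length(x$z), max(x$z), x$bias, x$gate))
  invisible(x)
}
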