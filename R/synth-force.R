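# Synthetic force-separation retraction curves with unbinding events.
#
# Each curve is a flat zero-force baseline with (optionally) one sawtooth
# unbinding event: the load grows linearly at the effective stiffness until
# the rupture force is reached at the rupture length, then drops
# discontinuously back to baseline. Rupture forces are drawn either from a
# truncated Gaussian or from the Bell-Evans first-passage density at the
# loading rate r = k_eff * v, sampled through its analytic inverse CDF.

#' Gaussian rupture-force model
#' @param center,width Center and s.d. in pN.
#' @return Model spec for [force_gen_config()].
#' @export
rupture_gaussian <- function(center, width) {
  if (center <= 0 || width < 0) abort("invalid gaussian rupture model", "smelt_config_error")
  structure(list(type = "gaussian", center = center, width = width),
            class = "rupture_model")
}

#' Bell-Evans rupture-force model
#' @param k0_u Zero-force unbinding rate in 1/s.
#' @param x_u Distance to the unbinding barrier in nm.
#' @param temperature Temperature in K.
#' @return Model spec for [force_gen_config()].
#' @export
rupture_bell_evans <- function(k0_u, x_u, temperature = 298) {
  if (k0_u <= 0 || x_u <= 0 || temperature <= 0)
    abort("invalid bell-evans rupture model", "smelt_config_error")
  structure(list(type = "bell_evans", k0_u = k0_u, x_u = x_u,
                 temperature = temperature),
            class = "rupture_model")
}

# Inverse-CDF sampler for the Bell-Evans first-passage force density
#   p(F) = (k0/r) e^{xF/kT} exp[-(k0 kT/(x r))(e^{xF/kT} - 1)]
# CDF(F) = 1 - exp[-(k0 kT/(x r))(e^{xF/kT} - 1)], so
#   F(u) = (kT/x) ln(1 - (x r/(k0 kT)) ln(1 - u)).
sample_bell_evans_force <- function(n, k0_u, x_u, loading_rate, temperature = 298) {
  kbt <- thermal_energy(temperature)
  u <- runif(n)
  (kbt / x_u) * log(1 - (x_u * loading_rate / (k0_u * kbt)) * log(1 - u))
}

#' Configuration for synthetic force-separation curves
#'
#' @param rupture_model A [rupture_gaussian()] or [rupture_bell_evans()] spec.
#' @param pulling_velocity Retraction velocity in um/s.
#' @param effective_stiffness Effective spring constant in pN/nm; the loading
#'   rate is `effective_stiffness * pulling_velocity` (pN/s with v in nm/s).
#' @param tether_contour_length Linker contour length in nm (0 for direct
#'   attachment); a nonzero value offsets the rupture-length distribution.
#' @param rupture_length_center,rupture_length_width Rupture-length
#'   distribution (nm).
#' @param fraction_with_event Probability that a curve contains an event.
#' @param max_separation Retraction span in nm.
#' @param points_per_curve Samples per curve.
#' @param noise_sd Additive force noise s.d. in pN.
#' @param n_curves Number of curves.
#' @param seed Integer seed (optional).
#' @return Object of class `force_gen_config`.
#' @export
force_gen_config <- function(rupture_model = rupture_gaussian(55, 17),
                             pulling_velocity = 1,
                             effective_stiffness = 56,
                             tether_contour_length = 0,
                             rupture_length_center = 12,
                             rupture_length_width = 3,
                             fraction_with_event = 1,
                             max_separation = 30,
                             points_per_curve = 1024,
                             noise_sd = 5,
                             n_curves = 200,
                             seed = NULL) {
  if (!inherits(rupture_model, "rupture_model"))
    abort("rupture_model must be rupture_gaussian() or rupture_bell_evans()",
          "smelt_config_error")
  if (fraction_with_event < 0 || fraction_with_event > 1)
    abort("fraction_with_event must be in [0, 1]", "smelt_config_error")
  if (pulling_velocity <= 0 || effective_stiffness <= 0)
    abort("loading rate k_eff * v must be positive", "smelt_config_error")
  if (max_separation <= 0 || points_per_curve < 2 || noise_sd < 0 || n_curves < 1)
    abort("invalid curve geometry", "smelt_config_error")
  structure(list(rupture_model = rupture_model,
                 pulling_velocity = pulling_velocity,
                 effective_stiffness = effective_stiffness,
                 tether_contour_length = tether_contour_length,
                 rupture_length_center = rupture_length_center,
                 rupture_length_width = rupture_length_width,
                 fraction_with_event = fraction_with_event,
                 max_separation = max_separation,
                 points_per_curve = points_per_curve,
                 noise_sd = noise_sd, n_curves = n_curves, seed = seed),
            class = "force_gen_config")
}

#' Generate synthetic force-separation retraction curves
#'
#' @param config A [force_gen_config()].
#' @return List of `force_curve` objects (class `force_ensemble`), each with
#'   `separation` (nm), `force` (pN, adhesion negative), `pulling_velocity`,
#'   `cantilever_stiffness`, and generator truth in `metadata` (`has_event`,
#'   `f_rupture`, `l_rupture`, `loading_rate`).
#' @export
gen_force_curves <- function(config) {
  stopifnot(inherits(config, "force_gen_config"))
  with_seed(config$seed, {
    v_nm <- config$pulling_velocity * 1000   # um/s -> nm/s
    r <- config$effective_stiffness * v_nm   # pN/s
    sep <- seq(0, config$max_separation, length.out = config$points_per_curve)
    m <- config$rupture_model
    curves <- vector("list", config$n_curves)
    for (i in seq_len(config$n_curves)) {
      has_event <- runif(1) < config$fraction_with_event
      force <- numeric(length(sep))
      fr <- NA_real_; lr <- NA_real_
      if (has_event) {
        fr <- switch(m$type,
          gaussian = rnorm_pos(1, m$center, m$width),
          bell_evans = sample_bell_evans_force(1, m$k0_u, m$x_u, r, m$temperature))
        lr <- rnorm_pos(1, config$rupture_length_center + config$tether_contour_length,
                        config$rupture_length_width,
                        lower = fr / config$effective_stiffness)
        lr <- min(lr, config$max_separation * 0.9)
        s0 <- lr - fr / config$effective_stiffness
        ramp <- sep > s0 & sep <= lr
        force[ramp] <- -(sep[ramp] - s0) * config$effective_stiffness
      }
      if (config$noise_sd > 0) force <- force + rnorm(length(sep), sd = config$noise_sd)
      curves[[i]] <- structure(
        list(separation = sep, force = force,
             pulling_velocity = config$pulling_velocity,
             cantilever_stiffness = config$effective_stiffness,
             metadata = list(has_event = has_event, f_rupture = fr,
                             l_rupture = lr, loading_rate = r)),
        class = "force_curve")
    }
    structure(curves, class = "force_ensemble")
  })
}
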