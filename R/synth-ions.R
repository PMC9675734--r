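# Synthetic monovalent-ion coordinate frames around fixed charged sites.
#
# Frames are independent equilibrium draws: each of N ions (N set by the bulk
# concentration and box volume) is placed with Boltzmann weight
# exp(-q phi(x)) where phi is the linearized-screening (Debye-Hueckel)
# potential of the configured site charges in kT/e. Water is implicit -- the
# dielectric continuum enters through the Bjerrum and Debye lengths. A 0.3 nm
# hard core around each site regularizes the point-charge divergence. With no
# site charges, placement is uniform.

#' Configuration for synthetic ion frames
#'
#' @param box_dimensions Box edge lengths in nm (length-3).
#' @param bulk_concentration Bulk ion concentration in M.
#' @param site_charges Data frame with columns `x`, `y`, `z` (nm, absolute
#'   box coordinates) and `q` (site charge in e); may have zero rows.
#' @param ion_charge Charge of the sampled ions in e (+1 for cations).
#' @param temperature Temperature in K.
#' @param relative_permittivity Solvent relative permittivity.
#' @param n_frames Number of frames.
#' @param core_radius Hard-core exclusion radius around sites in nm.
#' @param seed Integer seed (optional).
#' @return Object of class `ion_gen_config`.
#' @export
ion_gen_config <- function(box_dimensions = c(8, 8, 8),
                           bulk_concentration = 0.05,
                           site_charges = data.frame(
                             x = c(2.4, 5.6), y = c(4, 4), z = c(4, 4),
                             q = c(1, 1)),
                           ion_charge = 1,
                           temperature = 298,
                           relative_permittivity = 78.5,
                           n_frames = 200,
                           core_radius = 0.3,
                           seed = NULL) {
  if (length(box_dimensions) != 3L || any(box_dimensions <= 0))
    abort("box must have three positive edge lengths", "smelt_config_error")
  if (bulk_concentration < 0)
    abort("bulk concentration must be non-negative", "smelt_config_error")
  sc <- as.data.frame(site_charges)
  if (nrow(sc) > 0 && !all(c("x", "y", "z", "q") %in% names(sc)))
    abort("site_charges needs x, y, z, q columns", "smelt_config_error")
  if (n_frames < 1 || temperature <= 0 || relative_permittivity <= 0)
    abort("invalid sampler settings", "smelt_config_error")
  structure(list(box_dimensions = box_dimensions,
                 bulk_concentration = bulk_concentration,
                 site_charges = sc, ion_charge = ion_charge,
                 temperature = temperature,
                 relative_permittivity = relative_permittivity,
                 n_frames = n_frames, core_radius = core_radius, seed = seed),
            class = "ion_gen_config")
}

#' Generate ion coordinate frames by rejection sampling
#'
#' @param config An [ion_gen_config()].
#' @return Object of class `ion_trajectory`: `frames` (list of N x 3
#'   coordinate matrices in Angstrom), `box_dimensions` (Angstrom),
#'   `ion_charge`, `n_frames`, plus the generating config in `metadata`.
#' @export
gen_ion_frames <- function(config) {
  stopifnot(inherits(config, "ion_gen_config"))
  with_seed(config$seed, {
    box <- config$box_dimensions
    vol_L <- prod(box) * 1e-24                      # nm^3 -> L
    n_ions <- round(config$bulk_concentration * .const$NA_mol * vol_L)
    ionic_strength <- max(config$bulk_concentration, 1e-4)
    sc <- config$site_charges

    weight <- function(xyz) {
      if (nrow(sc) == 0L) return(rep(1, nrow(xyz)))
      phi <- dh_potential(xyz, sc,
                          ionic_strength = ionic_strength,
                          temperature = config$temperature,
                          eps_r = config$relative_permittivity,
                          core_radius = config$core_radius)
      exp(-config$ion_charge * phi)
    }

    # bound the Boltzmann factor on a coarse grid (core radius caps it)
    w_max <- 1
    if (nrow(sc) > 0L) {
      gr <- expand.grid(x = seq(0, box[1], length.out = 25),
                        y = seq(0, box[2], length.out = 25),
                        z = seq(0, box[3], length.out = 25))
      w_max <- max(weight(as.matrix(gr)))
      core_pts <- as.matrix(sc[, c("x", "y", "z")])
      w_max <- max(w_max, weight(core_pts)) * 1.05
    }

    frames <- vector("list", config$n_frames)
    accepted <- 0; proposed <- 0
    for (f in seq_len(config$n_frames)) {
      if (n_ions == 0L) { frames[[f]] <- matrix(numeric(0), 0, 3); next }
      pts <- matrix(numeric(0), 0, 3)
      while (nrow(pts) < n_ions) {
        m <- max(2L * (n_ions - nrow(pts)), 32L)
        cand <- cbind(runif(m, 0, box[1]), runif(m, 0, box[2]), runif(m, 0, box[3]))
        acc <- runif(m) < weight(cand) / w_max
        proposed <- proposed + m
        accepted <- accepted + sum(acc)
        pts <- rbind(pts, cand[acc, , drop = FALSE])
        if (proposed > 1e4 && accepted / proposed < 0.01)
          abort("rejection acceptance rate below 1%: pathological field",
                "smelt_pathological_field")
      }
      frames[[f]] <- pts[seq_len(n_ions), , drop = FALSE] * 10  # nm -> Angstrom
    }
    structure(list(frames = frames, box_dimensions = box * 10,
                   ion_charge = config$ion_charge,
                   n_frames = config$n_frames,
                   metadata = list(config = config,
                                   acceptance_rate = if (proposed > 0) accepted / proposed else NA_real_)),
              class = "ion_trajectory")
  })
}
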