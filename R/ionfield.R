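# Ion concentration maps, linearized-screening electrostatics, and
# diffusion-limited association rates.
#
# The electrostatic field is the linearized Debye-Hueckel superposition of
# screened Coulomb terms -- a closed-form stand-in for a nonlinear
# Poisson-Boltzmann solver, adequate for the qualitative conduit contrast
# (depletion vs accumulation of counterions between two charged sites).
# Association rates come from a centrosymmetric two-body estimator: Brownian
# trajectories between an inner launch surface b and an outer escape surface
# q, assembled into rates with the Northrup-Allison-McCammon formula against
# quadrature-based diffusion-limited rates.

#' Screened-Coulomb (Debye-Hueckel) potential at arbitrary points
#'
#' `phi(x) = sum_i q_i l_B exp(-d_i / lambda_D) / d_i` in kT/e units, with
#' `l_B` the Bjerrum length and distances in nm. Distances below
#' `core_radius` are clamped to it, which regularizes the point-charge
#' divergence.
#'
#' @param points N x 3 matrix of coordinates in nm.
#' @param charges Data frame with `x`, `y`, `z` (nm) and `q` (e).
#' @param ionic_strength Ionic strength in M (>= 0; 0 gives bare Coulomb).
#' @param temperature Temperature in K.
#' @param eps_r Relative permittivity.
#' @param core_radius Distance clamp in nm (0 disables clamping).
#' @return Potential in kT/e at each point.
#' @export
dh_potential <- function(points, charges, ionic_strength,
                         temperature = 298, eps_r = 78.5, core_radius = 0) {
  if (ionic_strength < 0)
    abort("ionic strength must be non-negative", "smelt_config_error")
  pts <- as.matrix(points)
  lb <- bjerrum_length(temperature, eps_r)
  ld <- debye_length(ionic_strength, temperature, eps_r)
  phi <- numeric(nrow(pts))
  for (i in seq_len(nrow(charges))) {
    d <- sqrt((pts[, 1] - charges$x[i])^2 +
              (pts[, 2] - charges$y[i])^2 +
              (pts[, 3] - charges$z[i])^2)
    if (core_radius > 0) d <- pmax(d, core_radius)
    scr <- if (is.finite(ld)) exp(-d / ld) else 1
    phi <- phi + charges$q[i] * lb * scr / d
  }
  phi
}

#' Debye-Hueckel potential field on a regular grid
#'
#' @param charges Data frame with `x`, `y`, `z` (Angstrom) and `q` (e).
#' @param origin Grid origin in Angstrom (length-3).
#' @param dims Number of voxels along each axis (length-3).
#' @param voxel_edge Voxel edge in Angstrom.
#' @inheritParams dh_potential
#' @param contour_spacing Spacing of equipotential contours in kT/e
#'   (default 0.2).
#' @return Object of class `potential_field`: `origin`, `voxel_edge`,
#'   `values` (3D array, kT/e; voxels inside the core radius of a charge are
#'   `NA` and flagged in `excluded`), `debye_length` (nm),
#'   `contour_spacing`, and `contour_levels` spanning the field range.
#' @export
dh_field <- function(charges, origin = c(0, 0, 0), dims = c(40, 40, 40),
                     voxel_edge = 2, ionic_strength = 0.05,
                     temperature = 298, eps_r = 78.5,
                     contour_spacing = 0.2, core_radius = 1) {
  centers <- lapply(1:3, function(a)
    origin[a] + (seq_len(dims[a]) - 0.5) * voxel_edge)
  gr <- as.matrix(expand.grid(x = centers[[1]], y = centers[[2]], z = centers[[3]]))
  ch_nm <- data.frame(x = charges$x / 10, y = charges$y / 10,
                      z = charges$z / 10, q = charges$q)
  phi <- dh_potential(gr / 10, ch_nm, ionic_strength, temperature, eps_r)
  # flag voxels at/inside the core of any charge
  excl <- rep(FALSE, nrow(gr))
  for (i in seq_len(nrow(charges))) {
    d <- sqrt((gr[, 1] - charges$x[i])^2 + (gr[, 2] - charges$y[i])^2 +
              (gr[, 3] - charges$z[i])^2)
    excl <- excl | d < core_radius
  }
  phi[excl] <- NA_real_
  vals <- array(phi, dim = dims)
  rng <- range(phi, na.rm = TRUE)
  levels <- seq(floor(rng[1] / contour_spacing) * contour_spacing,
                ceiling(rng[2] / contour_spacing) * contour_spacing,
                by = contour_spacing)
  structure(list(origin = origin, voxel_edge = voxel_edge, values = vals,
                 excluded = array(excl, dim = dims),
                 debye_length = debye_length(ionic_strength, temperature, eps_r),
                 contour_spacing = contour_spacing, contour_levels = levels),
            class = "potential_field")
}

#' Voxelized mean ion concentration map
#'
#' Per-voxel mean occupancy over frames converted to molarity,
#' `c = <N> / (N_A V_voxel)`. The sum of `c * V_voxel * N_A` over voxels
#' equals the mean ion count per frame (conservation).
#'
#' @param traj An `ion_trajectory` (coordinates in Angstrom).
#' @param voxel_edge Voxel edge in Angstrom (default 1).
#' @return Object of class `density_grid`: `origin` (Angstrom),
#'   `voxel_edge`, `values` (3D array of molarity), `n_frames_averaged`,
#'   `contour_spacing` (0.15 M by default, following concentration-map
#'   practice).
#' @export
density_map <- function(traj, voxel_edge = 1) {
  box <- traj$box_dimensions
  if (any(voxel_edge > box))
    abort("voxel larger than the box", "smelt_invalid_grid")
  dims <- pmax(1L, ceiling(box / voxel_edge))
  counts <- array(0, dim = dims)
  for (fr in traj$frames) {
    if (nrow(fr) == 0L) next
    ix <- pmin(pmax(1L, 1L + floor(fr[, 1] / voxel_edge)), dims[1])
    iy <- pmin(pmax(1L, 1L + floor(fr[, 2] / voxel_edge)), dims[2])
    iz <- pmin(pmax(1L, 1L + floor(fr[, 3] / voxel_edge)), dims[3])
    idx <- cbind(ix, iy, iz)
    tab <- table(idx[, 1] + dims[1] * (idx[, 2] - 1L) +
                 dims[1] * dims[2] * (idx[, 3] - 1L))
    counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] + as.numeric(tab)
  }
  mean_n <- counts / traj$n_frames
  v_voxel_L <- voxel_edge^3 * 1e-27  # Angstrom^3 -> L
  values <- mean_n / (.const$NA_mol * v_voxel_L)
  structure(list(origin = c(0, 0, 0), voxel_edge = voxel_edge,
                 values = values, n_frames_averaged = traj$n_frames,
                 contour_spacing = 0.15),
            class = "density_grid")
}

#' Rectangular prism specification
#'
#' @param center Prism center in Angstrom (length-3).
#' @param edge_lengths Edge lengths in Angstrom (grid units of 1 Angstrom).
#' @return Object of class `prism_spec` with derived `volume_nm3`
#'   (`prod(edge_lengths)/1000`); e.g. 15 x 43 x 20 Angstrom gives 12.9 nm^3.
#' @export
prism_spec <- function(center, edge_lengths) {
  if (length(center) != 3L || length(edge_lengths) != 3L ||
      any(edge_lengths <= 0))
    abort("prism needs a 3D center and positive edges", "smelt_config_error")
  structure(list(center = center, edge_lengths = edge_lengths,
                 volume_nm3 = prod(edge_lengths) / 1000),
            class = "prism_spec")
}

#' Volume-weighted mean concentration inside a prism
#'
#' Voxels partially covered by the prism are weighted by their overlap
#' fraction along each axis.
#'
#' @param grid A `density_grid`.
#' @param prism A [prism_spec()] fully inside the grid.
#' @return Mean molarity (M) over the prism.
#' @export
prism_average <- function(grid, prism) {
  stopifnot(inherits(grid, "density_grid"), inherits(prism, "prism_spec"))
  dims <- dim(grid$values)
  e <- grid$voxel_edge
  lo <- prism$center - prism$edge_lengths / 2
  hi <- prism$center + prism$edge_lengths / 2
  gmax <- grid$origin + dims * e
  if (any(lo < grid$origin - 1e-9) || any(hi > gmax + 1e-9))
    abort("prism extends outside the grid", "smelt_out_of_bounds")
  axis_w <- function(a) {
    edges_lo <- grid$origin[a] + (seq_len(dims[a]) - 1) * e
    edges_hi <- edges_lo + e
    pmax(0, pmin(edges_hi, hi[a]) - pmax(edges_lo, lo[a]))
  }
  wx <- axis_w(1); wy <- axis_w(2); wz <- axis_w(3)
  w <- outer(outer(wx, wy), wz)
  sum(w * grid$values) / sum(w)
}

# Diffusion-limited rate to an absorbing sphere of radius r_nm under the
# (radial) potential u_kt(r) [kT], by quadrature of the centrosymmetric
# integral k_D(r) = 4 pi D / int_r^Inf exp(u(s))/s^2 ds. Returns 1/(M s).
smoluchowski_rate <- function(r_nm, u_kt, diffusion) {
  integrand <- function(s) exp(u_kt(s)) / s^2
  I <- integrate(integrand, lower = r_nm, upper = Inf,
                 rel.tol = 1e-9)$value          # 1/nm
  kd_m3s <- 4 * pi * diffusion / (I * 1e9)       # m^3/s
  kd_m3s * .const$NA_mol * 1e3                   # 1/(M s)
}

#' Association rates from centrosymmetric Brownian trajectories
#'
#' Trajectories are launched on a sphere of radius `b_surface` and stepped by
#' Euler-Maruyama in 3D under the radial potential `u` until they either
#' reach the smallest reaction distance (recombination) or escape past
#' `q_surface`. The recombination probability P(d) at each reaction distance
#' is converted to a rate with the Northrup-Allison-McCammon expression
#' `k(d) = k_D(b) P(d) / (1 - (1 - P(d)) k_D(b)/k_D(q))`, where k_D is the
#' quadrature-based diffusion-limited rate.
#'
#' @param u Radial interaction potential, a function of distance in nm
#'   returning energy in kT (`NULL` for free diffusion).
#' @param diffusion Relative diffusion coefficient in m^2/s.
#' @param b_surface,q_surface Launch and escape radii in nm.
#' @param reaction_distances Reaction criteria in nm (all < `b_surface`);
#'   0.6 nm is the contact criterion, 2.5 nm the ET-trigger criterion.
#' @param n_trajectories Number of trajectories.
#' @param step_nm Target r.m.s. step length in nm.
#' @param max_steps Safety cap on steps per batch.
#' @param seed Integer seed (optional).
#' @return Object of class `rate_curve`: data frame columns
#'   `reaction_distance` (nm), `p_reach`, `rate` (1/(M s)), `mc_se` (rate
#'   Monte-Carlo s.e.), plus attributes `k_on_at_contact` (0.6 nm, if
#'   requested) and `k_trigger` (2.5 nm, if requested).
#' @export
bd_rate_curve <- function(u = NULL, diffusion = 1e-9,
                          b_surface = 3, q_surface = 10,
                          reaction_distances = c(0.6, 1.0, 1.5, 2.5),
                          n_trajectories = 500,
                          step_nm = 0.05, max_steps = 2e5, seed = NULL) {
  if (any(reaction_distances >= b_surface) || b_surface >= q_surface)
    abort("need reaction_distances < b_surface < q_surface", "smelt_config_error")
  u_kt <- if (is.null(u)) function(r) 0 * r else u
  d_nm2 <- diffusion * 1e18                      # nm^2/s
  dt <- step_nm^2 / (2 * d_nm2)
  dmin <- min(reaction_distances)

  # step-size sanity: |dU| per step must stay below 1 kT
  rr <- seq(dmin, q_surface, length.out = 400)
  du <- abs(diff(vapply(rr, u_kt, 1))) / diff(rr)
  if (any(is.finite(du) & du * step_nm * 3 > 1))
    abort("step size gives |dU| > kT per step; reduce step_nm",
          "smelt_step_too_large")

  grad_u <- function(r) {
    h <- 1e-4
    (vapply(r + h, u_kt, 1) - vapply(r - h, u_kt, 1)) / (2 * h)
  }

  with_seed(seed, {
    # launch isotropically on the b sphere
    n <- n_trajectories
    zdir <- runif(n, -1, 1); th <- runif(n, 0, 2 * pi)
    rho <- sqrt(1 - zdir^2)
    pos <- b_surface * cbind(rho * cos(th), rho * sin(th), zdir)
    min_r <- rep(b_surface, n)
    alive <- rep(TRUE, n)
    sq <- sqrt(2 * d_nm2 * dt)
    steps <- 0L
    while (any(alive) && steps < max_steps) {
      steps <- steps + 1L
      idx <- which(alive)
      p <- pos[idx, , drop = FALSE]
      r <- sqrt(rowSums(p^2))
      g <- grad_u(r)
      disp <- -d_nm2 * dt * g                     # radial drift displacement (nm)
      p <- p * (1 + disp / r) + matrix(rnorm(3 * length(idx), sd = sq), ncol = 3)
      rnew <- sqrt(rowSums(p^2))
      pos[idx, ] <- p
      min_r[idx] <- pmin(min_r[idx], rnew)
      done <- rnew <= dmin | rnew >= q_surface
      alive[idx[done]] <- FALSE
    }

    kd_b <- smoluchowski_rate(b_surface, u_kt, diffusion)
    kd_q <- smoluchowski_rate(q_surface, u_kt, diffusion)
    res <- lapply(sort(reaction_distances, decreasing = TRUE), function(d) {
      pd <- mean(min_r <= d)
      denom <- 1 - (1 - pd) * kd_b / kd_q
      rate <- kd_b * pd / denom
      se_p <- sqrt(pd * (1 - pd) / n)
      # first-order propagation of the MC error in P(d)
      dk_dp <- kd_b * (1 - kd_b / kd_q) / denom^2
      data.frame(reaction_distance = d, p_reach = pd, rate = rate,
                 mc_se = abs(dk_dp) * se_p)
    })
    out <- do.call(rbind, res)
    out <- out[order(out$reaction_distance), , drop = FALSE]
    rownames(out) <- NULL
    k06 <- out$rate[match(0.6, out$reaction_distance)]
    k25 <- out$rate[match(2.5, out$reaction_distance)]
    structure(out, k_on_at_contact = k06, k_trigger = k25,
              kd_b = kd_b, kd_q = kd_q, n_trajectories = n,
              class = c("rate_curve", "data.frame"))
  })
}
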