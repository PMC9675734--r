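# Ion density maps, screened electrostatics, association rates.

test_that("a pinned ion converts to 1.661 M in its voxel", {
  traj <- structure(list(frames = rep(list(matrix(c(5, 5, 5), 1, 3)), 10),
                         box_dimensions = c(10, 10, 10), ion_charge = 1,
                         n_frames = 10, metadata = list()),
                    class = "ion_trajectory")
  g <- density_map(traj, voxel_edge = 10)
  expect_equal(max(g$values), 1.661, tolerance = 1e-3)
  expect_equal(sum(g$values > 0), 1L)
})

test_that("density maps conserve the mean ion count", {
  cfg <- ion_gen_config(n_frames = 50, seed = 3)
  tr <- gen_ion_frames(cfg)
  n_per_frame <- nrow(tr$frames[[1]])
  for (edge in c(8, 20)) {
    g <- density_map(tr, voxel_edge = edge)
    total <- sum(g$values) * (edge^3 * 1e-27) * 6.02214076e23
    expect_equal(total, n_per_frame, tolerance = 1e-9)
  }
  expect_error(density_map(tr, voxel_edge = 1000), class = "smelt_invalid_grid")
  # empty frames -> all-zero grid
  tr0 <- gen_ion_frames(ion_gen_config(bulk_concentration = 0, n_frames = 2,
                                       seed = 1))
  expect_true(all(density_map(tr0, voxel_edge = 10)$values == 0))
})

test_that("prism averages weight partial voxels and respect bounds", {
  expect_equal(prism_spec(c(0, 0, 0), c(15, 43, 20))$volume_nm3, 12.9)
  vals <- array(0.05, dim = c(8, 8, 8))
  g <- structure(list(origin = c(0, 0, 0), voxel_edge = 10, values = vals,
                      n_frames_averaged = 1, contour_spacing = 0.15),
                 class = "density_grid")
  expect_equal(prism_average(g, prism_spec(c(40, 40, 40), c(15, 43, 20))), 0.05)
  # a prism equal to one voxel returns that voxel's value
  vals2 <- vals; vals2[3, 4, 5] <- 0.5
  g2 <- g; g2$values <- vals2
  pv <- prism_average(g2, prism_spec(c(25, 35, 45), c(10, 10, 10)))
  expect_equal(pv, 0.5)
  expect_error(prism_average(g, prism_spec(c(100, 40, 40), c(15, 43, 20))),
               class = "smelt_out_of_bounds")
})

test_that("Debye-Hueckel field has the right screening length and symmetries", {
  expect_equal(debye_length(0.05), 1.36, tolerance = 0.01)
  expect_equal(debye_length(0.05), 0.304 / sqrt(0.05), tolerance = 0.01)
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  pts <- matrix(c(1, 0, 0), 1, 3)
  phi <- dh_potential(pts, ch, ionic_strength = 0.05)
  # sign flip negates the field exactly (linearity)
  chm <- ch; chm$q <- -1
  expect_equal(dh_potential(pts, chm, 0.05), -phi, tolerance = 1e-14)
  # I -> 0 reduces to bare Coulomb at 1 nm
  phi0 <- dh_potential(pts, ch, ionic_strength = 0)
  expect_equal(phi0, bjerrum_length(), tolerance = 1e-6)
  fld <- dh_field(data.frame(x = 20, y = 20, z = 20, q = 1),
                  dims = c(20, 20, 20), voxel_edge = 2, core_radius = 2)
  expect_equal(fld$debye_length, 1.36, tolerance = 0.01)
  expect_true(any(fld$excluded))
  expect_true(all(is.na(fld$values[fld$excluded])))
})

test_that("sampled ion densities are Boltzmann-consistent with the field", {
  # regression of ln c on phi over all adequately sampled voxels; the free
  # intercept absorbs the fixed-N normalization of the sampler
  cfg <- ion_gen_config(box_dimensions = c(6, 6, 6), bulk_concentration = 0.1,
                        site_charges = data.frame(x = c(1.8, 4.2), y = c(3, 3),
                                                  z = c(3, 3), q = c(1, 1)),
                        n_frames = 4000, seed = 19)
  tr <- gen_ion_frames(cfg)
  g <- density_map(tr, voxel_edge = 7.5)
  d <- dim(g$values)
  centers <- lapply(1:3, function(a) ((seq_len(d[a]) - 0.5) * 7.5) / 10)
  gr <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  phi <- dh_potential(gr, cfg$site_charges, ionic_strength = 0.1,
                      core_radius = 0.3)
  c_obs <- as.vector(g$values)  # expand.grid varies dim 1 fastest, matching R arrays
  keep <- c_obs > 0
  fit <- lm(log(c_obs[keep]) ~ phi[keep])
  expect_equal(coef(fit)[[2]], -cfg$ion_charge, tolerance = 0.1)
})

test_that("depletion direction between like-charged sites reverses with charge sign", {
  mid <- prism_spec(center = c(40, 40, 40), edge_lengths = c(15, 20, 20))
  pos <- ion_gen_config(seed = 2, n_frames = 300)  # two +1 sites, +1 ions
  gp <- density_map(gen_ion_frames(pos), voxel_edge = 5)
  expect_lt(prism_average(gp, mid), 0.05)
  neg <- ion_gen_config(site_charges = data.frame(x = c(2.4, 5.6), y = c(4, 4),
                                                  z = c(4, 4), q = c(-1, -1)),
                        seed = 2, n_frames = 300)
  gn <- density_map(gen_ion_frames(neg), voxel_edge = 5)
  expect_gt(prism_average(gn, mid), 0.05)
})

test_that("free-diffusion Brownian rates match the Smoluchowski closed form", {
  rc <- bd_rate_curve(NULL, diffusion = 1e-9, b_surface = 2, q_surface = 6,
                      reaction_distances = c(0.6, 1.0, 1.5),
                      n_trajectories = 600, step_nm = 0.03, seed = 8)
  for (i in seq_len(nrow(rc))) {
    k_exact <- 4 * pi * 1e-9 * rc$reaction_distance[i] * 1e-9 *
      6.02214076e23 * 1e3
    expect_lt(abs(rc$rate[i] - k_exact), 3 * rc$mc_se[i] + 0.03 * k_exact)
  }
  # rates are non-increasing with stricter criteria
  expect_true(all(diff(rc$rate) >= 0))
})

test_that("attraction raises association rates above free diffusion", {
  u_attr <- function(r) -2 * exp(-r / 1.36) * 1.36 / r  # screened attraction, kT
  free <- bd_rate_curve(NULL, b_surface = 2, q_surface = 6,
                        reaction_distances = 0.6, n_trajectories = 400,
                        step_nm = 0.04, seed = 9)
  attr_rc <- bd_rate_curve(u_attr, b_surface = 2, q_surface = 6,
                           reaction_distances = 0.6, n_trajectories = 400,
                           step_nm = 0.04, seed = 9)
  expect_gt(attr_rc$rate, free$rate)
  # quadrature oracle under the same potential
  k_quad <- smelt:::smoluchowski_rate(0.6, u_attr, 1e-9)
  expect_lt(abs(attr_rc$rate - k_quad), 3 * attr_rc$mc_se + 0.05 * k_quad)
})

test_that("step-size guard trips on violently varying potentials", {
  u_bad <- function(r) 100 / r^6
  expect_error(bd_rate_curve(u_bad, b_surface = 2, q_surface = 6,
                             reaction_distances = 0.6, n_trajectories = 10,
                             step_nm = 0.05, seed = 1),
               class = "smelt_step_too_large")
})
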