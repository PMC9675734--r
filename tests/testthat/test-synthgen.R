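# Synthetic-data generators: closed-form values in the noiseless limit,
# seeded determinism, and embedded ground truth.

test_that("noiseless I-z curves follow I_sp exp(-beta z) + I_leak exactly", {
  cfg <- iz_gen_config(noise_fraction = 0, n_curves = 1, seed = 7)
  cv <- gen_iz_ensemble(cfg)[[1]]
  expect_equal(cv$current, 0.4 * exp(-1.3 * cv$z) + 0.002, tolerance = 1e-12)
  # direct evaluation at z = 1 nm
  i1 <- 0.4 * exp(-1.3) + 0.002
  expect_equal(stats::approx(cv$z, cv$current, xout = 1)$y, i1, tolerance = 1e-4)
  expect_equal(round(i1, 4), 0.1110)
  expect_equal(cv$metadata$beta_true, 1.3)
})

test_that("component weights are respected at large n", {
  cfg <- iz_gen_config(
    beta_components = data.frame(center = c(1.3, 3.1), sd = c(0.2, 0.4),
                                 weight = c(0.22, 0.78)),
    points_per_curve = 2, n_curves = 4000, seed = 11)
  comp <- vapply(gen_iz_ensemble(cfg), function(cv) cv$metadata$component, 1L)
  expect_equal(mean(comp == 1L), 0.22, tolerance = 0.1)
})

test_that("invalid I-z configurations are rejected", {
  expect_error(iz_gen_config(retraction_length = 0), class = "smelt_config_error")
  expect_error(iz_gen_config(beta_components = data.frame(center = 1, sd = 0, weight = 0.5)),
               class = "smelt_config_error")
  expect_error(iz_gen_config(leakage_current = 0.5), class = "smelt_config_error")
})

test_that("generators are bit-reproducible given a seed", {
  a <- gen_iz_ensemble(iz_gen_config(seed = 42, n_curves = 3))
  b <- gen_iz_ensemble(iz_gen_config(seed = 42, n_curves = 3))
  expect_identical(a, b)
  ta <- gen_blink_trace(blink_gen_config(seed = 42, trace_duration = 1))
  tb <- gen_blink_trace(blink_gen_config(seed = 42, trace_duration = 1))
  expect_identical(ta, tb)
  fa <- gen_force_curves(force_gen_config(seed = 42, n_curves = 3))
  fb <- gen_force_curves(force_gen_config(seed = 42, n_curves = 3))
  expect_identical(fa, fb)
  sa <- gen_sensograms(spr_gen_config(seed = 42, noise_sd = 1))
  sb <- gen_sensograms(spr_gen_config(seed = 42, noise_sd = 1))
  expect_identical(sa, sb)
  ia <- gen_ion_frames(ion_gen_config(seed = 42, n_frames = 3))
  ib <- gen_ion_frames(ion_gen_config(seed = 42, n_frames = 3))
  expect_identical(ia, ib)
})

test_that("blink amplitude is G * G0 * V and dwell statistics are exponential", {
  expect_equal(blink_amplitude(4.3e-6, 0.8), 4.3e-6 * 77.5e-6 * 0.8 * 1e9,
               tolerance = 1e-12)
  expect_equal(blink_amplitude(4.3e-6, 0.8), 0.2666, tolerance = 1e-3)
  cfg <- blink_gen_config(mean_blink_lifetime = 0.02, mean_interblink_time = 0.08,
                          trace_duration = 60, sampling_rate = 5e3, seed = 5)
  tr <- gen_blink_trace(cfg)
  expect_gt(nrow(tr$events), 400)
  # CLT check on the embedded ground-truth dwells
  n_ev <- nrow(tr$events)
  expect_lt(abs(mean(tr$events$lifetime) - 0.02), 4 * 0.02 / sqrt(n_ev))
  gaps <- diff(tr$events$onset) - head(tr$events$lifetime, -1)
  expect_lt(abs(mean(gaps) - 0.08), 4 * 0.08 / sqrt(n_ev))
})

test_that("infinite interblink time yields a blink-free trace", {
  cfg <- blink_gen_config(mean_interblink_time = Inf, noise_sd = 0,
                          trace_duration = 1, seed = 1)
  tr <- gen_blink_trace(cfg)
  expect_equal(nrow(tr$events), 0L)
  expect_true(all(tr$current == cfg$baseline_current))
})

test_that("unresolvable blink sampling warns", {
  expect_warning(blink_gen_config(sampling_rate = 100, mean_blink_lifetime = 0.01),
                 "unresolvable")
})

test_that("Bell-Evans force sampling matches the closed-form mode", {
  # mode of the first-passage density = most probable force
  set.seed(3)
  f <- smelt:::sample_bell_evans_force(2e4, 48, 0.31, 224000)
  expect_equal(most_probable_force(48, 0.31, 224000), 77.8, tolerance = 1e-3)
  d <- stats::density(f)
  expect_equal(d$x[which.max(d$y)], 77.8, tolerance = 0.05)
})

test_that("event-free and Gaussian force ensembles behave as configured", {
  none <- gen_force_curves(force_gen_config(fraction_with_event = 0,
                                            n_curves = 10, seed = 2))
  expect_true(all(!vapply(none, function(cv) cv$metadata$has_event, TRUE)))
  g <- gen_force_curves(force_gen_config(rupture_model = rupture_gaussian(55, 17),
                                         n_curves = 400, seed = 2))
  fr <- vapply(g, function(cv) cv$metadata$f_rupture, 1)
  expect_equal(mean(fr), 55, tolerance = 0.05)
})

test_that("sensograms obey the Langmuir closed forms", {
  # half-saturation identity at C = KD
  kd <- 3.18e-3 / 6.54e3
  cfg <- spr_gen_config(concentrations = kd, association_duration = 5000,
                        dissociation_duration = 0)
  sg <- gen_sensograms(cfg)[[1]]
  expect_equal(max(sg$response), cfg$rmax / 2, tolerance = 1e-3)
  # observed association rate from the mutant row
  expect_equal(1.00e4 * 5e-6 + 3.58e-3, 0.0536, tolerance = 1e-3)
  # noiseless dissociation decays to zero
  cfg2 <- spr_gen_config(dissociation_duration = 1e4)
  sg2 <- gen_sensograms(cfg2)[[1]]
  expect_lt(sg2$response[length(sg2$response)], 1e-8 * cfg2$rmax)
})

test_that("ion frames: uniform limit, depletion direction, empty limits", {
  nosites <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        q = numeric(0))
  tr <- gen_ion_frames(ion_gen_config(site_charges = nosites, n_frames = 200,
                                      seed = 4))
  g <- density_map(tr, voxel_edge = 40)
  expect_equal(mean(g$values), 0.05, tolerance = 0.05)
  # zero bulk -> empty frames
  tr0 <- gen_ion_frames(ion_gen_config(bulk_concentration = 0, n_frames = 2,
                                       site_charges = nosites, seed = 1))
  expect_true(all(vapply(tr0$frames, nrow, 1L) == 0L))
  # cations accumulate between two negative sites (Boltzmann attraction)
  neg <- ion_gen_config(site_charges = data.frame(x = c(2.4, 5.6), y = c(4, 4),
                                                  z = c(4, 4), q = c(-1, -1)),
                        n_frames = 300, seed = 4)
  gn <- density_map(gen_ion_frames(neg), voxel_edge = 5)
  mid <- prism_spec(center = c(40, 40, 40), edge_lengths = c(15, 20, 20))
  expect_gt(prism_average(gn, mid), 0.05)
})
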