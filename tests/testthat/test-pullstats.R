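# Rupture detection, force statistics and Bell-Evans inference.

test_that("a constructed sawtooth yields one event at the set force and length", {
  cv <- make_sawtooth_curve(f_r = 55, l_r = 12)
  ev <- detect_ruptures(cv)
  expect_equal(nrow(ev), 1L)
  spacing_load <- 56 * diff(cv$separation[1:2])
  expect_equal(ev$f_rupture, 55, tolerance = spacing_load / 55)
  expect_equal(ev$l_rupture, 12, tolerance = 0.01)
  expect_equal(ev$loading_rate, 56 * 1000, tolerance = 0.01)
})

test_that("smooth curves without discontinuities yield no events", {
  cv <- make_sawtooth_curve()
  cv$force <- -20 * sin(seq(0, pi, length.out = length(cv$force)))  # smooth adhesion
  expect_equal(nrow(detect_ruptures(cv)), 0L)
})

test_that("detection is near-complete with sub-sigma force accuracy", {
  # rupture forces >= 5x the 2 pN noise
  cfg <- force_gen_config(rupture_model = rupture_gaussian(55, 8),
                          noise_sd = 2, n_curves = 150, seed = 31)
  curves <- gen_force_curves(cfg)
  ev <- detect_ruptures_ensemble(curves)
  truth <- vapply(curves, function(cv) cv$metadata$f_rupture, 1)
  expect_gte(nrow(ev), 0.99 * length(curves))
  err <- ev$f_rupture - truth[ev$curve]
  expect_lt(median(abs(err)), 2)
  # recovered rupture lengths match the generator distribution
  lr_truth <- vapply(curves, function(cv) cv$metadata$l_rupture, 1)
  ks <- suppressWarnings(stats::ks.test(ev$l_rupture, lr_truth[ev$curve]))
  expect_gt(ks$p.value, 0.01)
})

test_that("median detected loading rate equals k_eff * v", {
  cfg <- force_gen_config(n_curves = 100, seed = 5)
  ev <- detect_ruptures_ensemble(gen_force_curves(cfg))
  expect_equal(median(ev$loading_rate), 56000, tolerance = 0.1)
})

test_that("force_distribution reports Gaussian center, width and mean", {
  set.seed(41)
  x <- rep(100, 50)
  fd <- force_distribution(x)
  expect_equal(fd$center, 100)
  expect_equal(fd$mean, 100)
  draws <- smelt:::rnorm_pos(500, 55, 17)
  fd2 <- force_distribution(draws)
  expect_equal(fd2$center, 55, tolerance = 0.1)
  expect_error(force_distribution(rnorm(10, 55, 5)),
               class = "smelt_insufficient_data")
})

test_that("most probable force matches the closed form and clamps at zero", {
  expect_equal(most_probable_force(48, 0.31, 28000), 50.2, tolerance = 1e-3)
  expect_equal(most_probable_force(48, 0.31, 224000), 77.8, tolerance = 1e-3)
  kbt <- thermal_energy(298)
  expect_equal(most_probable_force(48, 0.31, 48 * kbt / 0.31), 0)
  expect_error(most_probable_force(-1, 0.31, 1e4), class = "smelt_domain_error")
})

test_that("Bell-Evans fit is the exact inverse of the force law", {
  rates <- c(28000, 56000, 112000, 224000)
  forces <- most_probable_force(48, 0.31, rates)
  fit <- suppressWarnings(bell_evans_fit(rates, forces))
  expect_equal(fit$k0_u, 48, tolerance = 1e-10)
  expect_equal(fit$x_u, 0.31, tolerance = 1e-10)
  expect_equal(fit$regime, "kinetic")
  # algebraic round trip holds for arbitrary parameters
  for (p in list(c(5, 0.1), c(500, 0.8))) {
    f2 <- suppressWarnings(
      bell_evans_fit(rates, most_probable_force(p[1], p[2], rates)))
    expect_equal(f2$k0_u, p[1], tolerance = 1e-8)
    expect_equal(f2$x_u, p[2], tolerance = 1e-8)
  }
})

test_that("noisy Bell-Evans points recover parameters within 20%", {
  rates <- c(28000, 56000, 112000, 224000)
  truth <- most_probable_force(48, 0.31, rates)
  ok <- 0L
  set.seed(51)
  for (i in 1:20) {
    fit <- bell_evans_fit(rates, truth + rnorm(4, sd = 2))
    if (is.finite(fit$k0_u) &&
        abs(fit$k0_u - 48) / 48 < 0.5 && abs(fit$x_u - 0.31) / 0.31 < 0.2)
      ok <- ok + 1L
  }
  expect_gte(ok, 14L)  # median-style recovery across seeds
})

test_that("regime classification separates flat from log-linear force scaling", {
  rates <- c(28000, 56000, 112000, 224000)
  flat <- bell_evans_fit(rates, rep(55, 4))
  expect_equal(flat$regime, "near_equilibrium")
  expect_equal(classify_regime(flat), "near_equilibrium")
  set.seed(6)
  noisy_flat <- bell_evans_fit(rates, 55 + rnorm(4, sd = 3))
  expect_equal(classify_regime(noisy_flat), "near_equilibrium")
  kin <- suppressWarnings(bell_evans_fit(rates, most_probable_force(48, 0.31, rates)))
  expect_equal(classify_regime(kin), "kinetic")
  expect_error(bell_evans_fit(rates[1:2], c(50, 60)),
               class = "smelt_insufficient_data")
})
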