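# Decay-factor extraction, population modelling and group comparison.

test_that("noiseless decay fit recovers beta to machine-level precision", {
  cfg <- iz_gen_config(noise_fraction = 0, n_curves = 1, seed = 1)
  cv <- gen_iz_ensemble(cfg)[[1]]
  f <- fit_decay(cv)
  expect_equal(f$beta, 1.3, tolerance = 1e-7)
  expect_equal(f$leakage, 0.002, tolerance = 1e-5)
  expect_gt(f$r_squared, 0.999999)
})

test_that("flat curves at the leakage floor raise NoDecayRegion", {
  flat <- list(z = seq(0, 15, length.out = 100), current = rep(0.002, 100))
  expect_error(fit_decay(flat), class = "smelt_no_decay_region")
})

test_that("beta is invariant to leakage shifts and covariant under current scaling", {
  cfg <- iz_gen_config(noise_fraction = 0, n_curves = 1, seed = 2)
  cv <- gen_iz_ensemble(cfg)[[1]]
  f0 <- fit_decay(cv)
  shifted <- cv; shifted$current <- cv$current + 0.01
  f1 <- fit_decay(shifted)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-6)
  scaled <- cv; scaled$current <- cv$current * 3
  f2 <- fit_decay(scaled)
  expect_equal(f2$beta, f0$beta, tolerance = 1e-6)
  expect_equal(f2$amplitude, 3 * f0$amplitude, tolerance = 1e-5)
  expect_equal(f2$leakage, 3 * f0$leakage, tolerance = 1e-4)
})

test_that("Monte-Carlo recovery: median beta within 5% of truth at 10% noise", {
  for (beta_true in c(1.3, 3.1)) {
    cfg <- iz_gen_config(beta_components = data.frame(center = beta_true,
                                                      sd = 0, weight = 1),
                         noise_fraction = 0.10, n_curves = 100, seed = 9)
    fits <- fit_decay_ensemble(gen_iz_ensemble(cfg))
    expect_equal(median(fits$beta), beta_true, tolerance = 0.05)
  }
})

test_that("mixture modelling recovers unimodal and bimodal populations", {
  set.seed(21)
  uni <- rnorm(1000, 1.3, 0.8)
  pu <- fit_beta_population(uni)
  expect_equal(pu$n_components, 1L)
  expect_equal(pu$centers, 1.3, tolerance = 0.1)
  bi <- c(rnorm(220, 1.3, 0.2), rnorm(780, 3.1, 0.4))
  pb <- fit_beta_population(bi)
  expect_equal(pb$n_components, 2L)
  expect_equal(pb$weights, c(0.22, 0.78), tolerance = 0.15)
  expect_equal(pb$centers, c(1.3, 3.1), tolerance = 0.05)
})

test_that("BIC model choice is stable across replicates", {
  # unimodal truth -> 1 component; well-separated truth -> 2 components
  n_uni <- 0L; n_bi <- 0L; reps <- 20L
  set.seed(33)
  for (i in seq_len(reps)) {
    u <- rnorm(300, 2, 0.5)
    n_uni <- n_uni + (fit_beta_population(u)$n_components == 1L)
    b <- c(rnorm(150, 1.3, 0.2), rnorm(150, 3.1, 0.4))  # > 3 s.d. apart
    n_bi <- n_bi + (fit_beta_population(b)$n_components == 2L)
  }
  expect_gte(n_uni, ceiling(0.95 * reps))
  expect_gte(n_bi, ceiling(0.95 * reps))
})

test_that("degenerate and undersized beta sets are handled", {
  expect_error(fit_beta_population(rnorm(10)), class = "smelt_insufficient_data")
  pd <- fit_beta_population(rep(1.3, 25))
  expect_equal(pd$n_components, 1L)
  expect_equal(pd$widths, 0)
})

test_that("beta_vs_gate aggregates, drops singletons, and finds the minimum", {
  # parabolic gate profile with a minimum of 0.5 nm^-1 at -0.25 V
  gates <- seq(-0.45, 0.05, by = 0.1)
  set.seed(8)
  df <- do.call(rbind, lapply(gates, function(g) {
    mu <- 0.5 + 8 * (g + 0.25)^2
    data.frame(gate = g, beta = rnorm(80, mu, 0.05))
  }))
  tab <- beta_vs_gate(df$gate, df$beta)
  expect_equal(attr(tab, "gate_min"), -0.25)
  expect_equal(tab$n, rep(80L, length(gates)))
  expect_equal(tab$mean_beta[tab$gate == -0.25], 0.5, tolerance = 0.05)
  # flat profile stays flat within its s.d.
  flat <- beta_vs_gate(df$gate, rnorm(nrow(df), 1.3, 0.1))
  expect_true(all(abs(flat$mean_beta - 1.3) < flat$sd_beta))
  # singleton groups are rejected, others kept
  mix <- beta_vs_gate(c(rep(-0.1, 5), 0.2), c(rnorm(5, 1), 2))
  expect_equal(mix$gate, -0.1)
})

test_that("pooled t-test matches hand computation and conventions", {
  tt <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4L)
  base <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(tt$t, unname(base$statistic))
  expect_equal(tt$p_value, base$p.value)
  # df convention n_a + n_b - 2
  expect_equal(compare_groups(rnorm(134), rnorm(88))$df, 220L)
  # identical groups -> t = 0 even with zero variance
  expect_equal(compare_groups(rep(1, 5), rep(1, 5))$t, 0)
})
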