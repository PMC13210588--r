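test_that("identical realizations give a zero-width confidence band", {
  run <- run_ensemble(param_set("set1", sigma1 = 0), initial_condition("ic1"),
                      time_grid(0, 10, 501), n_real = 4, base_seed = 1)
  s <- ensemble_summary(run)
  expect_true(all(s$sd_z1 == 0))
  expect_true(all(s$ci_high_z1 == s$ci_low_z1))
  expect_true(all(s$ci_low_z1 <= s$mean_z1 & s$mean_z1 <= s$ci_high_z1))
})

test_that("the ensemble mean recovers the level of synthetic constant paths", {
  set.seed(42)
  run <- const_ensemble(rnorm(200, mean = 1, sd = 0.5))
  s <- ensemble_summary(run)
  expect_lt(abs(s$mean_z1[1] - 1), 3 * 0.5 / sqrt(200))
  expect_error(ensemble_summary(const_ensemble(1)), "at least 2")
})

test_that("the model ensemble variance stays bounded over the run", {
  run <- run_ensemble(param_set("set1", sigma1 = 0.1),
                      initial_condition("ic1"),
                      default_stoch_grid(), n_real = 50, base_seed = 42)
  s <- ensemble_summary(run)
  expect_true(all(is.finite(s$var_z1)))
  expect_lt(max(s$var_z1), 5)
})

test_that("confidence-band width shrinks like one over sqrt(n)", {
  set.seed(9)
  levels <- rnorm(800)
  w <- vapply(c(50, 200), function(n) {
    s <- ensemble_summary(const_ensemble(levels[seq_len(n)]))
    mean(s$ci_high_z1 - s$ci_low_z1)
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 0.15)
})

test_that("noise-free ensembles deviate nowhere from the deterministic path", {
  grid <- time_grid(0, 20, 1001)
  p0 <- param_set("set1", sigma1 = 0)
  det <- integrate_deterministic(p0, initial_condition("ic1"), grid)
  run <- run_ensemble(p0, initial_condition("ic1"), grid, n_real = 3,
                      base_seed = 1)
  cmp <- compare_det_stoch(det, run)
  # explicit Euler vs adaptive integration differ slightly, but sigma = 0
  # makes all members identical, so member deviation equals mean-path deviation
  expect_equal(cmp$dev_z1, cmp$mean_path_dev_z1)
  run2 <- run_ensemble(param_set("set1", sigma1 = 0.1),
                       initial_condition("ic1"), grid, n_real = 10,
                       base_seed = 1)
  cmp2 <- compare_det_stoch(det, run2)
  expect_true(all(cmp2$dev_z1 >= 0))
  # triangle inequality: the mean path deviates no more than the mean deviation
  expect_true(all(cmp2$mean_path_dev_z1 <= cmp2$dev_z1 + 1e-12))
  expect_error(compare_det_stoch(integrate_deterministic(
    p0, initial_condition("ic1"), time_grid(0, 20, 500)), run2),
    "share the time grid")
})

test_that("the fast variable is the noise-sensitive one", {
  grid <- default_stoch_grid()
  p <- param_set("set1", sigma1 = 0.1)
  det <- integrate_deterministic(param_set("set1"), initial_condition("ic1"),
                                 grid)
  run <- run_ensemble(p, initial_condition("ic1"), grid, n_real = 50,
                      base_seed = 42)
  cmp <- compare_det_stoch(det, run)
  expect_gt(cmp$avg_dev_z1, cmp$avg_dev_z2)
  d1 <- final_time_distribution(run, "z1")
  d2 <- final_time_distribution(run, "z2")
  expect_gt(d1$sigma, d2$sigma)
})

test_that("final-time fits recover known Gaussian parameters", {
  set.seed(31)
  run <- const_ensemble(rnorm(1000, 0, 1))
  d <- final_time_distribution(run, "z1")
  expect_lt(abs(d$mu), 0.1)
  expect_lt(abs(d$sigma - 1), 0.1)
  expect_equal(sum(d$counts), 1000)

  # degenerate ensemble: all members identical
  dg <- final_time_distribution(const_ensemble(rep(2.5, 20)), "z1",
                                det_ref = 2.5)
  expect_equal(dg$sigma, 0)
  expect_equal(dg$mu, 2.5)
  expect_length(dg$counts, 1)
  expect_error(final_time_distribution(const_ensemble(rnorm(5)), "z1"),
               "at least 10")
})

test_that("final-time distributions do not depend on member order", {
  set.seed(8)
  levels <- rnorm(100)
  a <- final_time_distribution(const_ensemble(levels), "z1")
  b <- final_time_distribution(const_ensemble(sample(levels)), "z1")
  expect_equal(a$mu, b$mu)
  expect_equal(a$sigma, b$sigma)
})

test_that("spike detection finds threshold crossings with a refractory gap", {
  tau <- seq(0, 10, by = 0.1)
  x <- sin(2 * pi * 0.5 * tau)       # period 2: five upward crossings of 0.5
  st <- spike_times(x, tau, threshold = 0.5)
  expect_equal(length(st), 5)
  expect_equal(diff(st), rep(2, 4), tolerance = 0.1)
})

test_that("interval regularity matches closed-form interval statistics", {
  # strictly periodic clock: zero interval spread
  clock <- make_spike_train(100, isi = 1, jitter = 0)
  expect_equal(sd(diff(clock)), 0)
  expect_identical(isi_regularity(diff(clock)), Inf)

  # Poisson train: exponential intervals have mean == sd, so R ~ 1
  pois <- make_spike_train(10000, rate = 1, seed = 4)
  expect_lt(abs(isi_regularity(diff(pois)) - 1), 0.05)

  # jitter ordering: 5% jitter is ~4x more regular than 20% jitter
  j05 <- make_spike_train(5000, isi = 1, jitter = 0.05, seed = 10)
  j20 <- make_spike_train(5000, isi = 1, jitter = 0.20, seed = 10)
  expect_gt(isi_regularity(diff(j05)), isi_regularity(diff(j20)))

  expect_identical(isi_regularity(numeric(1)), NA_real_)
})

test_that("the coherence scan returns a regularity curve over noise levels", {
  cs <- coherence_scan(param_set("set1"), initial_condition("ic1"),
                       grid = time_grid(0, 60, 3001),
                       sigmas = c(0.05, 0.1), n_real = 3, base_seed = 42)
  expect_equal(cs$curve$sigma, c(0.05, 0.1))
  expect_true(all(is.na(cs$curve$regularity) | cs$curve$regularity >= 0))
  expect_true(is.finite(cs$threshold))
  expect_error(coherence_scan(param_set("set1"), initial_condition("ic1"),
                              sigmas = c(0.2, 0.1), n_real = 2), "increasing")
})
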