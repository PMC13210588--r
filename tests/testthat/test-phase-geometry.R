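test_that("energy series is the weighted quadratic form", {
  tr <- piezo_trajectory(c(0, 1), c(0, 1), c(0, 1))
  expect_equal(energy_series(tr), c(0, 1))
  # time-mean of half sin^2 is 1/4
  g <- time_grid(0, 100, 10001)
  sine <- piezo_trajectory(g$tau, sin(2 * pi * 0.1 * g$tau), rep(0, g$n_points))
  expect_equal(mean(energy_series(sine)), 0.25, tolerance = 0.01)
})

test_that("features of a pure sine recover the analytic values", {
  g <- time_grid(0, 150, 10001)
  s <- make_sine(amplitude = 1, freq = 0.1, grid = g)
  f <- signal_features(s, transient_cut = 0, attractor_window = 50)
  bin <- 1 / (150 * (10000 / 10001))   # one periodogram bin of the post-cut run
  expect_lt(abs(f$dominant_freq - 0.1), 2 * bin)
  expect_equal(f$hull_area, pi, tolerance = 0.01)
  # constant-radius orbit: energy is constant, so peak-to-peak ~ 0 and CV 0
  expect_equal(f$peak_to_peak, 0, tolerance = 1e-9)
  expect_equal(f$cv_amplitude, 0)
})

test_that("a constant trajectory yields degenerate features without error", {
  g <- time_grid(0, 10, 101)
  tr <- piezo_trajectory(g$tau, rep(1, 101), rep(0.5, 101))
  f <- signal_features(tr, transient_cut = 0)
  expect_equal(f$peak_to_peak, 0)
  expect_equal(f$cv_amplitude, 0)
  expect_equal(f$dominant_freq, 0)
})

test_that("hull area grows monotonically under point-set union", {
  set.seed(21)
  th <- runif(200, 0, 2 * pi)
  inner <- cbind(cos(th) * runif(200, 0, 1), sin(th) * runif(200, 0, 1))
  outer_pts <- cbind(cos(th) * runif(200, 1, 2), sin(th) * runif(200, 1, 2))
  a_inner <- hull_area(inner)
  a_union <- hull_area(rbind(inner, outer_pts))
  expect_gte(a_union, a_inner)
  expect_equal(hull_area(matrix(c(0, 0, 1, 1), 2, 2)), 0)  # degenerate
})

test_that("bistable toy basin labels equal the sign of the initial z1", {
  toy <- function(z1, z2, tau) list(z1 - z1^3, -z2)
  b <- basin_map(drift = toy, z1_range = c(-2, 2), z2_range = c(-2, 2),
                 N = 21, T_end = 10, dt = 0.05)
  ic_z1 <- matrix(b$z1_grid, 21, 21)        # rows index z1
  expect_identical(b$labels, sign(ic_z1))   # separatrix column at z1 = 0 -> 0
})

test_that("a globally contracting drift collapses every node to the origin", {
  contracting <- function(z1, z2, tau) list(-z1, -z2)
  T_end <- 10
  b <- basin_map(drift = contracting, z1_range = c(-2, 2), z2_range = c(-2, 2),
                 N = 15, T_end = T_end, dt = 0.05, label_tol = 1e-3)
  expect_lt(max(abs(b$final_z1)), exp(-T_end) * 2 * 1.01)
  expect_true(all(b$labels == 0))
})

test_that("the model basin map is finite at reduced resolution", {
  b <- basin_map(param_set("set1"), N = 30, T_end = 100, dt = 0.05)
  expect_true(all(is.finite(b$final_z1)))
  expect_equal(b$n_blown, 0)
})

test_that("basin labels at label-uniform interior nodes survive grid refinement", {
  # N = 30 -> N = 59 so the coarse nodes are an exact subset of the fine grid
  coarse <- basin_map(param_set("set1"), N = 30, T_end = 100, dt = 0.05)
  fine <- basin_map(param_set("set1"), N = 59, T_end = 100, dt = 0.05)
  checked <- 0L
  for (i in 2:29) {
    for (j in 2:29) {
      nb <- coarse$labels[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (length(unique(as.vector(nb))) == 1L) {
        checked <- checked + 1L
        expect_identical(fine$labels[2L * i - 1L, 2L * j - 1L],
                         coarse$labels[i, j])
      }
    }
  }
  expect_gt(checked, 50)  # the comparison must not be vacuous
})

test_that("an overflow-prone drift is caught by the blow-up guard", {
  exploding <- function(z1, z2, tau) list(z1^3 + 1, z2)
  expect_warning(
    b <- basin_map(drift = exploding, z1_range = c(1, 3), z2_range = c(-1, 1),
                   N = 5, T_end = 5, dt = 0.05),
    "blew up")
  expect_gt(b$n_blown, 0)
  expect_true(all(b$labels[b$final_z1 == 0] == 0))
  expect_true(all(is.finite(b$final_z1)))
})

test_that("zero perturbation yields zero divergence", {
  s <- sensitivity_divergence(param_set("set1"), initial_condition("ic1"),
                              delta = 0, grid = time_grid(0, 20, 1001))
  expect_true(all(s$dz1_series == 0))
  expect_equal(s$peak_value, 0)
})

test_that("small perturbations grow linearly at early times", {
  g <- time_grid(0, 5, 2001)
  s1 <- sensitivity_divergence(param_set("set1"), initial_condition("ic1"),
                               delta = 1e-4, grid = g)
  s2 <- sensitivity_divergence(param_set("set1"), initial_condition("ic1"),
                               delta = 2e-4, grid = g)
  early <- g$tau > 0.2 & g$tau < 1
  ratio <- mean(s2$dz1_series[early] / s1$dz1_series[early])
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("perturbed trajectories reconverge onto the shared attractor", {
  s <- sensitivity_divergence(param_set("set1"), initial_condition("ic1"),
                              delta = 0.01, grid = time_grid(0, 300, 10000))
  expect_lt(s$residual, s$peak_value)
})

test_that("return maps behave as analytic phase shifts on a sine", {
  g <- time_grid(0, 100, 4001)
  s <- make_sine(amplitude = 1, freq = 0.1, grid = g)
  r0 <- return_map(s, 0)
  expect_identical(r0$x, r0$y)

  quarter <- 2.5  # quarter of the 10-unit period, an exact number of steps
  rq <- return_map(s, quarter)
  expect_lt(max(abs(rq$x^2 + rq$y^2 - 1)), 1e-9)

  rf <- return_map(s, 10)
  expect_lt(max(abs(rf$x - rf$y)), 1e-9)

  expect_error(return_map(s, 1e6), "no pairs")
})

test_that("two delay applications compose into one doubled delay", {
  tr <- integrate_deterministic(param_set("set1"), initial_condition("ic1"),
                                time_grid(0, 60, 3001))
  zeta <- 1.5
  r1 <- return_map(tr, zeta)
  r2 <- return_map(tr, 2 * zeta)
  k <- r1$k
  n2 <- length(r2$x)
  expect_equal(r2$y, r1$y[(k + 1):(k + n2)])
  expect_equal(r2$x, r1$x[1:n2])
})

test_that("default delay ladder spans two forcing periods in sixths", {
  d <- default_delays(1.2)
  expect_length(d, 12)
  expect_equal(d[6], 2 * pi / 1.2)
  expect_equal(diff(d), rep(d[1], 11))
})

test_that("the energy-peak CV is unchanged under grid refinement", {
  cv_at <- function(n) {
    tr <- integrate_deterministic(param_set("set1"), initial_condition("ic1"),
                                  time_grid(0, 300, n))
    signal_features(tr, transient_cut = 100)$cv_amplitude
  }
  expect_identical(signif(cv_at(20000), 4), signif(cv_at(40000), 4))
})
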