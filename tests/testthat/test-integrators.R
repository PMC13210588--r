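test_that("adaptive integration matches the fixed-step RK4 oracle", {
  p <- param_set("set1")
  grid <- default_det_grid()
  tr <- integrate_deterministic(p, initial_condition("ic1"), grid)
  ref <- oracle_rk4(model_drift_fn(p), initial_condition("ic1"), grid$tau,
                    substeps = 16L)  # internal step ~0.001
  expect_lt(max(abs(tr$z1 - ref[, 1])), 1e-4)
  expect_lt(max(abs(tr$z2 - ref[, 2])), 1e-4)
})

test_that("starting at the autonomous fixed point stays there", {
  fp <- set1_fixed_point()
  p <- piezo_params(A = 0, u_pc = 0)
  atol <- 1.49e-8
  tr <- integrate_deterministic(p, fp, time_grid(0, 50, 2000), atol = atol)
  expect_lt(max(abs(tr$z1 - fp[["z1"]])), atol * 10)
  expect_lt(max(abs(tr$z2 - fp[["z2"]])), atol * 10)
})

test_that("restarting mid-run reproduces the tail (semigroup property)", {
  p <- param_set("set1")
  full <- integrate_deterministic(p, initial_condition("ic1"),
                                  time_grid(0, 300, 20001))
  i0 <- 10001L  # tau = 150 exactly
  tail_run <- integrate_deterministic(
    p, c(full$z1[i0], full$z2[i0]), time_grid(150, 300, 10001))
  expect_lt(max(abs(tail_run$z1 - full$z1[i0:20001])), 1e-6)
  expect_lt(max(abs(tail_run$z2 - full$z2[i0:20001])), 1e-6)
})

test_that("noise-free Euler-Maruyama equals explicit Euler exactly", {
  p <- param_set("set1", sigma1 = 0)
  grid <- time_grid(0, 50, 2501)
  em <- euler_maruyama(p, initial_condition("ic1"), grid, seed = 5)
  # independent explicit-Euler loop
  z1 <- numeric(grid$n_points); z2 <- numeric(grid$n_points)
  z1[1] <- 0.05; z2[1] <- -0.03
  for (i in seq_len(grid$n_points - 1L)) {
    t <- grid$tau[i]
    d1 <- z1[i] * (1 - p$psi) - z1[i]^3 / 3 - z2[i] + p$A * cos(p$Omega * t)
    d2 <- p$eta * (z1[i] + p$a - p$lam * z2[i])
    z1[i + 1] <- z1[i] + d1 * grid$dt
    z2[i + 1] <- z2[i] + d2 * grid$dt
  }
  expect_identical(em$z1, z1)
  expect_identical(em$z2, z2)
})

test_that("a fixed seed reproduces the stochastic path bit-for-bit", {
  p <- param_set("set1", sigma1 = 0.1)
  grid <- time_grid(0, 20, 1001)
  a <- euler_maruyama(p, initial_condition("ic1"), grid, seed = 42)
  b <- euler_maruyama(p, initial_condition("ic1"), grid, seed = 42)
  expect_identical(a$z1, b$z1)
  expect_identical(a$z2, b$z2)
  c_ <- euler_maruyama(p, initial_condition("ic1"), grid, seed = 43)
  expect_false(identical(a$z1, c_$z1))
})

test_that("ensembles are seeded per member and reproducible", {
  p <- param_set("set1", sigma1 = 0.1)
  grid <- time_grid(0, 10, 501)
  one <- run_ensemble(p, initial_condition("ic1"), grid, n_real = 1,
                      base_seed = 7)
  single <- euler_maruyama(p, initial_condition("ic1"), grid, seed = 7)
  expect_identical(one$z1[, 1], single$z1)

  e1 <- run_ensemble(p, initial_condition("ic1"), grid, n_real = 6,
                     base_seed = 42)
  e2 <- run_ensemble(p, initial_condition("ic1"), grid, n_real = 6,
                     base_seed = 42)
  expect_identical(e1$z1, e2$z1)
  expect_identical(e1$seeds, 42L + 0:5)

  # degenerate ensemble: all members coincide with the Euler path
  p0 <- param_set("set1", sigma1 = 0)
  e0 <- run_ensemble(p0, initial_condition("ic1"), grid, n_real = 5,
                     base_seed = 42)
  for (i in 2:5) expect_identical(e0$z1[, i], e0$z1[, 1])
})

test_that("Euler-Maruyama endpoint error halves when the step is halved", {
  # Additive noise: refining against a path built from summed fine increments.
  p <- param_set("set1", sigma1 = 0.1)
  drift <- function(z1, z2, tau) {
    list(z1 * (1 - p$psi) - z1^3 / 3 - z2 + p$A * cos(p$Omega * tau),
         p$eta * (z1 + p$a - p$lam * z2))
  }
  T1 <- 10
  nf <- 3200L
  ratios <- vapply(1:20, function(s) {
    set.seed(s)
    dWf <- rnorm(nf, 0, sqrt(T1 / nf))
    tauf <- seq(0, T1, length.out = nf + 1L)
    ref <- em_path(drift, c(0.05, -0.03), tauf, p$sigma1, dW = dWf)
    endpoint <- function(k) {
      dW <- colSums(matrix(dWf, nrow = k))
      tt <- seq(0, T1, length.out = nf / k + 1L)
      tr <- em_path(drift, c(0.05, -0.03), tt, p$sigma1, dW = dW)
      c(tr$z1[nrow(tr)], tr$z2[nrow(tr)])
    }
    refv <- c(ref$z1[nrow(ref)], ref$z2[nrow(ref)])
    e_coarse <- sqrt(sum((endpoint(8L) - refv)^2))
    e_fine <- sqrt(sum((endpoint(4L) - refv)^2))
    e_coarse / e_fine
  }, numeric(1))
  expect_gt(mean(ratios), 1.5)
  expect_lt(mean(ratios), 2.7)
})

test_that("with zero drift the stepper reproduces Wiener-path variance", {
  zero_drift <- function(z1, z2, tau) list(0, 0)
  sigma <- 0.5
  T1 <- 4
  tau <- seq(0, T1, length.out = 51)
  n_real <- 2000L
  set.seed(123)
  ends <- vapply(seq_len(n_real), function(i) {
    tr <- em_path(zero_drift, c(0, 0), tau, sigma, seed = 1000L + i)
    tr$z1[length(tau)]
  }, numeric(1))
  v <- var(ends)
  target <- sigma^2 * T1
  se <- target * sqrt(2 / (n_real - 1))
  expect_lt(abs(v - target), 3 * se)
})

test_that("all printed parameter sets and initial conditions stay bounded", {
  grid <- time_grid(0, 300, 20000)
  for (set in c("set1", "set2", "set3")) {
    for (icn in c("ic1", "ic2", "ic3")) {
      tr <- integrate_deterministic(param_set(set), initial_condition(icn),
                                    grid)
      expect_lt(max(abs(tr$z1), abs(tr$z2)), 10)
    }
  }
})

test_that("the ensemble-mean endpoint approaches the noise-free path as noise vanishes", {
  ic <- initial_condition("ic1")
  grid <- time_grid(0, 20, 1001)
  det_end <- euler_maruyama(param_set("set1", sigma1 = 0), ic, grid,
                            seed = 0)$z1[grid$n_points]
  devs <- vapply(c(0.1, 0.01, 0.001), function(s) {
    run <- run_ensemble(param_set("set1", sigma1 = s), ic, grid,
                        n_real = 30, base_seed = 42)
    abs(mean(run$z1[grid$n_points, ]) - det_end)
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("grid and seed validation reject degenerate input", {
  expect_error(time_grid(1, 1, 10), "t1 > t0")
  expect_error(time_grid(0, 1, 1), "n_points")
  expect_error(euler_maruyama(param_set("set1", sigma1 = 0.1),
                              initial_condition("ic1"), seed = -1), "seed")
})
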