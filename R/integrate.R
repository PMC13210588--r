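#' Adaptive deterministic integration of the forced oscillator
#'
#' Solves the harmonically forced system with the LSODA solver
#' (automatic stiff/non-stiff switching and step-size control, via
#' \pkg{deSolve}) and samples the solution on an equally spaced output grid.
#' Solver name and tolerances are recorded in the trajectory metadata.
#'
#' @param params A [piezo_params()] object.
#' @param ic Initial state `c(z1, z2)`.
#' @param grid A [time_grid()]; defaults to 20,000 points on `[0, 300]`.
#' @param rtol,atol Relative/absolute tolerances (default `1.49e-8`, the
#'   conventional adaptive-solver default, pinned for reproducibility).
#' @return A [piezo_trajectory()].
#' @examples
#' tr <- integrate_deterministic(param_set("set1"), initial_condition("ic1"),
#'                               time_grid(0, 30, 2000))
#' @export
integrate_deterministic <- function(params, ic, grid = default_det_grid(),
                                    rtol = 1.49e-8, atol = 1.49e-8) {
  stopifnot(inherits(params, "piezo_params"), inherits(grid, "time_grid"))
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  f <- function(t, y, parms) {
    list(c(y[1] * (1 - parms$psi) - y[1]^3 / 3 - y[2] +
             parms$A * cos(parms$Omega * t),
           parms$eta * (y[1] + parms$a - parms$lam * y[2])))
  }
  out <- deSolve::ode(y = unname(ic[1:2]), times = grid$tau, func = f,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  bad <- !stats::complete.cases(out)
  if (any(bad))
    stop("deterministic integration failed at tau = ", grid$tau[which(bad)[1]])
  piezo_trajectory(out[, 1], out[, 2], out[, 3],
                   meta = list(params = unclass(params), ic = unname(ic[1:2]),
                               solver = "lsoda", rtol = rtol, atol = atol))
}

#' Low-level Euler--Maruyama path with injectable drift and increments
#'
#' One stochastic path on the stepping grid `tau`:
#' `z1[i+1] = z1[i] + dz1 * dt + sigma1 * dW[i]`, `z2[i+1] = z2[i] + dz2 * dt`.
#' The drift is any planar field `drift(z1, z2, tau) -> list(dz1, dz2)`, so
#' closed-form test systems (e.g. zero drift, for which `z1` is a pure Wiener
#' path with variance `sigma1^2 * t`) exercise the exact stepper used for the
#' neuron model. Exactly one of `dW` or `seed` supplies the noise increments.
#'
#' @param drift Vectorized drift function.
#' @param ic Initial state `c(z1, z2)`.
#' @param tau Strictly increasing, equally spaced time vector.
#' @param sigma1 Noise intensity on `z1`.
#' @param dW Optional Wiener increments (length `length(tau) - 1`).
#' @param seed Optional integer seed used to draw `dW ~ N(0, dt)`.
#' @return A [piezo_trajectory()] on the stepping grid.
#' @export
em_path <- function(drift, ic, tau, sigma1, dW = NULL, seed = NULL) {
  n <- length(tau)
  dt <- (tau[n] - tau[1]) / (n - 1)
  if (is.null(dW)) {
    if (sigma1 > 0 && is.null(seed)) stop("either dW or seed is required")
    dW <- if (sigma1 > 0 || !is.null(seed)) {
      with_seed(seed, stats::rnorm(n - 1L, 0, sqrt(dt)))
    } else numeric(n - 1L)
  }
  if (length(dW) != n - 1L) stop("dW must have length(tau) - 1 elements")
  z1 <- numeric(n); z2 <- numeric(n)
  z1[1] <- ic[[1]]; z2[1] <- ic[[2]]
  for (i in seq_len(n - 1L)) {
    d <- drift(z1[i], z2[i], tau[i])
    z1[i + 1] <- z1[i] + d[[1]] * dt + sigma1 * dW[i]
    z2[i + 1] <- z2[i] + d[[2]] * dt
  }
  piezo_trajectory(tau, z1, z2,
                   meta = list(solver = "euler-maruyama", dt = dt,
                               sigma1 = sigma1, seed = seed))
}

#' Euler--Maruyama integration of the stochastic oscillator
#'
#' Additive Gaussian white noise of intensity `params$sigma1` enters the fast
#' variable `z1` only; the slow recovery variable is integrated
#' deterministically within each step. With `sigma1 = 0` the scheme reduces
#' exactly to explicit Euler. A fixed `seed` makes the path bit-reproducible;
#' the caller's RNG state is left untouched.
#'
#' @inheritParams integrate_deterministic
#' @param grid A [time_grid()]; output grid equals the stepping grid. Default:
#'   5,000 steps on `[0, 100]` (dt = 0.02).
#' @param seed Non-negative integer seed.
#' @param noise_on_z2 Exploratory switch adding independent noise of the same
#'   intensity to `z2`; off by default and excluded from all reference
#'   analyses.
#' @return A [piezo_trajectory()] with `params`, `seed` and `dt` in metadata.
#' @export
euler_maruyama <- function(params, ic, grid = default_stoch_grid(), seed = 42,
                           noise_on_z2 = FALSE) {
  stopifnot(inherits(params, "piezo_params"), inherits(grid, "time_grid"))
  if (length(seed) != 1L || seed < 0 || seed != round(seed))
    stop("seed must be a single non-negative integer")
  drift <- model_drift(params)
  tr <- if (!noise_on_z2) {
    em_path(drift, ic, grid$tau, params$sigma1, seed = as.integer(seed))
  } else {
    n <- grid$n_points
    W <- with_seed(as.integer(seed),
                   matrix(stats::rnorm(2L * (n - 1L), 0, sqrt(grid$dt)),
                          ncol = 2L))
    z1 <- numeric(n); z2 <- numeric(n)
    z1[1] <- ic[[1]]; z2[1] <- ic[[2]]
    for (i in seq_len(n - 1L)) {
      d <- drift(z1[i], z2[i], grid$tau[i])
      z1[i + 1] <- z1[i] + d[[1]] * grid$dt + params$sigma1 * W[i, 1]
      z2[i + 1] <- z2[i] + d[[2]] * grid$dt + params$sigma1 * W[i, 2]
    }
    piezo_trajectory(grid$tau, z1, z2, meta = list())
  }
  attr(tr, "meta") <- list(params = unclass(params), ic = unname(ic[1:2]),
                           solver = "euler-maruyama", dt = grid$dt,
                           seed = as.integer(seed), noise_on_z2 = noise_on_z2)
  tr
}

#' Seed-controlled ensemble of stochastic realizations
#'
#' Member `i` uses seed `base_seed + i - 1`, each drawn from its own generator
#' state, so ensembles are order-independent and any member can be regenerated
#' in isolation from the recorded seed list.
#'
#' @inheritParams euler_maruyama
#' @param n_real Number of realizations (>= 1; reference protocol uses 50).
#' @param base_seed First seed (default 42).
#' @return An object of class `piezo_ensemble`: shared `tau`, member matrices
#'   `z1`, `z2` (time x member), `seeds`, `sigma1`, `params`, `ic`.
#' @export
run_ensemble <- function(params, ic, grid = default_stoch_grid(),
                         n_real = 50, base_seed = 42) {
  stopifnot(n_real >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_real) - 1L
  z1 <- matrix(NA_real_, grid$n_points, n_real)
  z2 <- matrix(NA_real_, grid$n_points, n_real)
  for (i in seq_len(n_real)) {
    tr <- euler_maruyama(params, ic, grid, seed = seeds[i])
    z1[, i] <- tr$z1
    z2[, i] <- tr$z2
  }
  structure(list(tau = grid$tau, z1 = z1, z2 = z2, seeds = seeds,
                 sigma1 = params$sigma1, params = unclass(params),
                 ic = unname(ic[1:2]), dt = grid$dt),
            class = "piezo_ensemble")
}

#' @export
print.piezo_ensemble <- function(x, ...) {
  cat(sprintf("piezo_ensemble: %d realizations, %d time points, sigma1 = %g\n",
              ncol(x$z1), length(x$tau), x$sigma1))
  cat(sprintf("  seeds %d..%d, tau in [%g, %g]\n",
              x$seeds[1], x$seeds[length(x$seeds)],
              x$tau[1], x$tau[length(x$tau)]))
  invisible(x)
}

#' Extract one ensemble member as a trajectory
#' @param run A [run_ensemble()] result.
#' @param i Member index.
#' @return A [piezo_trajectory()].
#' @export
ensemble_member <- function(run, i) {
  stopifnot(inherits(run, "piezo_ensemble"), i >= 1, i <= ncol(run$z1))
  piezo_trajectory(run$tau, run$z1[, i], run$z2[, i],
                   meta = list(params = run$params, ic = run$ic,
                               solver = "euler-maruyama",
                               seed = run$seeds[i], sigma1 = run$sigma1))
}

# Evaluate thunk with a temporary RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

# Fixed-step classical RK4 for a vectorized planar drift; states may be
# vectors (one trajectory per element). Returns final state only unless
# save_every > 0, in which case a list of snapshots is returned.
rk4_drift <- function(drift, z1, z2, t0, n_steps, dt, guard = 1e6) {
  blown <- rep(FALSE, length(z1))
  for (s in seq_len(n_steps)) {
    t <- t0 + (s - 1) * dt
    k1 <- drift(z1, z2, t)
    k2 <- drift(z1 + dt / 2 * k1[[1]], z2 + dt / 2 * k1[[2]], t + dt / 2)
    k3 <- drift(z1 + dt / 2 * k2[[1]], z2 + dt / 2 * k2[[2]], t + dt / 2)
    k4 <- drift(z1 + dt * k3[[1]], z2 + dt * k3[[2]], t + dt)
    nz1 <- z1 + dt / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]])
    nz2 <- z2 + dt / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]])
    bad <- !is.finite(nz1) | !is.finite(nz2) |
           abs(nz1) > guard | abs(nz2) > guard
    newly <- bad & !blown
    if (any(newly)) {
      blown <- blown | newly
      nz1[blown] <- z1[blown]  # freeze blown nodes at their last finite state
      nz2[blown] <- z2[blown]
      nz1[!is.finite(nz1)] <- 0
      nz2[!is.finite(nz2)] <- 0
    } else {
      nz1[blown] <- z1[blown]
      nz2[blown] <- z2[blown]
    }
    z1 <- nz1; z2 <- nz2
  }
  list(z1 = z1, z2 = z2, blown = blown)
}
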