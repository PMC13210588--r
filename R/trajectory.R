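#' Uniform time grid
#'
#' Equally spaced sampling grid on `[t0, t1]` with `n_points` samples
#' (step `dt = (t1 - t0) / (n_points - 1)`). The deterministic default used
#' throughout is 20,000 points on `[0, 300]` (dt ~ 0.015); the stochastic
#' default is 5,000 steps on `[0, 100]` (5,001 points, dt = 0.02) -- for the
#' Euler--Maruyama stepper the output grid *is* the stepping grid.
#'
#' @param t0,t1 Interval endpoints, `t1 > t0`.
#' @param n_points Number of samples (>= 2).
#' @return An object of class `time_grid` with elements `t0`, `t1`, `n_points`,
#'   `dt` and the sample vector `tau`.
#' @export
time_grid <- function(t0 = 0, t1 = 300, n_points = 20000) {
  if (!is.numeric(t0) || !is.numeric(t1) || t1 <= t0)
    stop("need t1 > t0")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  structure(list(t0 = t0, t1 = t1, n_points = n_points,
                 dt = (t1 - t0) / (n_points - 1),
                 tau = seq(t0, t1, length.out = n_points)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: [%g, %g], %d points, dt = %g\n",
              x$t0, x$t1, x$n_points, x$dt))
  invisible(x)
}

# Default grids matching the reference simulation protocol.
default_det_grid <- function() time_grid(0, 300, 20000)
default_stoch_grid <- function() time_grid(0, 100, 5001)

#' Construct a trajectory object
#'
#' A trajectory is the universal currency between all analysis stages: a
#' strictly increasing time vector `tau` with state series `z1`, `z2`, plus a
#' `meta` attribute recording provenance (parameters, solver, tolerances,
#' seed). Integrators and synthetic-signal generators share this constructor,
#' so every producer is validated identically.
#'
#' @param tau,z1,z2 Equal-length numeric vectors; `tau` strictly increasing,
#'   all values finite.
#' @param meta Named list of provenance fields.
#' @return A data frame of class `piezo_trajectory` with columns
#'   `tau`, `z1`, `z2`.
#' @export
piezo_trajectory <- function(tau, z1, z2, meta = list()) {
  n <- length(tau)
  if (length(z1) != n || length(z2) != n)
    stop("tau, z1, z2 must have equal length")
  if (n < 2L) stop("trajectory needs at least 2 samples")
  if (!all(is.finite(tau)) || !all(is.finite(z1)) || !all(is.finite(z2)))
    stop("trajectory values must all be finite")
  if (any(diff(tau) <= 0)) stop("tau must be strictly increasing")
  structure(data.frame(tau = tau, z1 = z1, z2 = z2),
            meta = meta,
            class = c("piezo_trajectory", "data.frame"))
}

#' @export
print.piezo_trajectory <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("piezo_trajectory: %d samples, tau in [%g, %g]\n",
              nrow(x), x$tau[1], x$tau[nrow(x)]))
  if (!is.null(m$solver)) cat("  solver:", m$solver, "\n")
  if (!is.null(m$seed)) cat("  seed:", m$seed, "\n")
  cat(sprintf("  z1 in [%.4g, %.4g], z2 in [%.4g, %.4g]\n",
              min(x$z1), max(x$z1), min(x$z2), max(x$z2)))
  invisible(x)
}

#' Trajectory metadata
#' @param traj A [piezo_trajectory()].
#' @return The `meta` list.
#' @export
trajectory_meta <- function(traj) attr(traj, "meta")

# Grid step of a (uniform) trajectory.
trajectory_dt <- function(traj) {
  dt <- diff(traj$tau)
  if (diff(range(dt)) > 1e-9 * max(dt))
    warning("trajectory grid is not uniform; using the mean step")
  mean(dt)
}

#' Drop the initial transient of a trajectory
#'
#' @param traj A [piezo_trajectory()].
#' @param transient_cut Keep samples with `tau >= transient_cut`.
#' @return A [piezo_trajectory()] restricted to the post-transient segment.
#' @export
cut_transient <- function(traj, transient_cut) {
  keep <- traj$tau >= transient_cut
  if (sum(keep) < 2L) stop("transient_cut removes (almost) the whole trajectory")
  piezo_trajectory(traj$tau[keep], traj$z1[keep], traj$z2[keep],
                   meta = c(trajectory_meta(traj),
                            list(transient_cut = transient_cut)))
}

#' Uniform-stride downsampling of a trajectory
#'
#' Used before recurrence analysis, whose cost is quadratic in the number of
#' samples. Indices are `round(seq(1, n, length.out = n_out))`; the realized
#' stride is recorded in the result's metadata.
#'
#' @param traj A [piezo_trajectory()].
#' @param n_out Number of output samples (<= `nrow(traj)`).
#' @return A [piezo_trajectory()] with `n_out` samples.
#' @export
downsample_trajectory <- function(traj, n_out = 2000) {
  n <- nrow(traj)
  if (n_out > n) stop("n_out exceeds trajectory length")
  idx <- unique(round(seq(1, n, length.out = n_out)))
  piezo_trajectory(traj$tau[idx], traj$z1[idx], traj$z2[idx],
                   meta = c(trajectory_meta(traj),
                            list(downsample_stride = n / n_out)))
}
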