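#' Delay return map of the fast variable
#'
#' Pairs `(z1(tau), z1(tau + zeta))` for all grid times where both samples
#' exist. The delay is rounded to the nearest whole number of grid steps; the
#' realized delay is returned alongside the requested one. Small delays
#' collapse the map onto the diagonal (short-term predictability); delays
#' comparable to the oscillation period trace closed loops for
#' (quasi-)periodic motion.
#'
#' @param traj A [piezo_trajectory()] on a uniform grid.
#' @param zeta Requested delay (dimensionless time, >= 0).
#' @return An object of class `return_map`: `x`, `y` sample vectors, `zeta`
#'   (requested), `zeta_actual`, and the step count `k`.
#' @export
return_map <- function(traj, zeta) {
  if (zeta < 0) stop("zeta must be >= 0")
  dt <- trajectory_dt(traj)
  k_num <- round(zeta / dt)
  n <- nrow(traj)
  if (k_num >= n)
    stop("delay of ", k_num, " steps leaves no pairs (series length ", n, ")")
  k <- as.integer(k_num)
  idx <- seq_len(n - k)
  structure(list(x = traj$z1[idx], y = traj$z1[idx + k],
                 zeta = zeta, zeta_actual = k * dt, k = k),
            class = "return_map")
}

#' @export
print.return_map <- function(x, ...) {
  cat(sprintf("return_map: zeta = %g (realized %g, %d steps), %d pairs\n",
              x$zeta, x$zeta_actual, x$k, length(x$x)))
  invisible(x)
}

#' Default ladder of return-map delays
#'
#' Twelve delays spanning two forcing periods in sixths:
#' `zeta_j = j * (2 pi / Omega) / 6`, `j = 1..n`.
#'
#' @param Omega Angular forcing frequency (> 0).
#' @param n Number of delays (default 12).
#' @return Numeric vector of delays.
#' @export
default_delays <- function(Omega, n = 12) {
  if (Omega <= 0) stop("Omega must be > 0")
  seq_len(n) * (2 * pi / Omega) / 6
}
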