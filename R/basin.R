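#' Basin-of-attraction map over a grid of initial conditions
#'
#' Integrates every node of an `N x N` grid of initial conditions with
#' fixed-step classical RK4 (all nodes advanced simultaneously, vectorized)
#' and classifies each node by the sign of `z1` at the fixed horizon `T`.
#' Defaults follow the reference protocol: `N = 300`, `T = 100`, `dt = 0.05`.
#' The drift is pluggable so closed-form toy systems (e.g. the bistable
#' `dz1 = z1 - z1^3`, `dz2 = -z2`) can validate the classifier exactly.
#'
#' @param params A [piezo_params()] used to build the model drift; ignored
#'   when `drift` is given.
#' @param drift Optional vectorized drift `function(z1, z2, tau)` returning
#'   `list(dz1, dz2)`.
#' @param z1_range,z2_range Grid bounds, length-2 each.
#' @param N Per-axis resolution (>= 2).
#' @param T_end Integration horizon.
#' @param dt RK4 step.
#' @param label_tol Final `|z1|` at or below this maps to label 0 (boundary).
#' @return An object of class `basin_grid`: grid axes `z1_grid`, `z2_grid`
#'   (rows of `final_z1` index `z1_grid`), matrices `final_z1` and `labels`
#'   (+1 / -1 / 0), the number of blown-up nodes, and the settings used.
#'   Nodes whose trajectory exceeds the overflow guard (1e6) are labelled 0
#'   and counted in `n_blown` (with a warning).
#' @export
basin_map <- function(params = NULL, drift = NULL,
                      z1_range = c(-2, 2), z2_range = c(-2, 2),
                      N = 300, T_end = 100, dt = 0.05, label_tol = 0) {
  if (is.null(drift)) {
    if (is.null(params)) stop("supply either params or drift")
    drift <- model_drift(params)
  }
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2")
  if (T_end <= 0 || dt <= 0) stop("T_end and dt must be > 0")
  g1 <- seq(z1_range[1], z1_range[2], length.out = N)
  g2 <- seq(z2_range[1], z2_range[2], length.out = N)
  ic <- expand.grid(z1 = g1, z2 = g2)  # z1 varies fastest -> column-major fill
  n_steps <- round(T_end / dt)
  res <- rk4_drift(drift, ic$z1, ic$z2, t0 = 0, n_steps = n_steps, dt = dt)
  final_z1 <- matrix(res$z1, N, N)     # [i, j] = IC (g1[i], g2[j])
  blown <- matrix(res$blown, N, N)
  labels <- sign(final_z1)
  labels[abs(final_z1) <= label_tol] <- 0
  labels[blown] <- 0
  final_z1[blown] <- 0
  if (any(blown))
    warning(sum(blown), " grid node(s) blew up and were labelled 0")
  structure(list(z1_grid = g1, z2_grid = g2,
                 final_z1 = final_z1, labels = labels,
                 n_blown = sum(blown),
                 T_end = T_end, dt = dt, label_tol = label_tol),
            class = "basin_grid")
}

#' @export
print.basin_grid <- function(x, ...) {
  N <- length(x$z1_grid)
  tab <- table(factor(x$labels, levels = c(-1, 0, 1)))
  cat(sprintf("basin_grid: %d x %d nodes, horizon T = %g, dt = %g\n",
              N, N, x$T_end, x$dt))
  cat(sprintf("  labels: %d negative, %d boundary, %d positive (%d blown)\n",
              tab[["-1"]], tab[["0"]], tab[["1"]], x$n_blown))
  invisible(x)
}
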