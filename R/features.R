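#' Quadratic energy of a trajectory
#'
#' `E(tau) = w1 * z1^2 + w2 * z2^2`, by default the symmetric storage function
#' `E = (z1^2 + z2^2) / 2`. The model prints no energy functional; this
#' simplest quadratic form is the package's fixed convention, and the weights
#' are exposed so alternative weightings can be explored. Downstream
#' regularity statistics (peak CV) are scale-free, so they do not depend on an
#' overall energy scale.
#'
#' @param traj A [piezo_trajectory()].
#' @param weights Length-2 non-negative weights for `z1^2` and `z2^2`.
#' @return Numeric vector `E(tau)`.
#' @export
energy_series <- function(traj, weights = c(0.5, 0.5)) {
  stopifnot(length(weights) == 2L, all(weights >= 0))
  weights[1] * traj$z1^2 + weights[2] * traj$z2^2
}

#' Prominence-filtered local maxima
#'
#' Strict 3-point local maxima, then a merge pass: a new candidate peak is
#' accepted only if the valley between it and the previously accepted peak
#' dips at least `prominence` below the lower of the two peaks; otherwise the
#' higher of the two survives. This suppresses float-noise double peaks while
#' keeping genuine oscillation maxima.
#'
#' @param x Numeric series.
#' @param prominence Minimum dip required between successive peaks (same units
#'   as `x`).
#' @return Integer indices of the retained peaks.
#' @export
find_peaks <- function(x, prominence = 0) {
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  if (length(cand) < 2L || prominence <= 0) return(cand)
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    valley <- min(x[last:i])
    if (min(x[i], x[last]) - valley >= prominence) {
      keep <- c(keep, i)
    } else if (x[i] > x[last]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

# Dominant frequency (cycles per unit time) of a mean-removed series via the
# raw periodogram; 0 for a (numerically) constant series.
dominant_frequency <- function(x, dt) {
  n <- length(x)
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12) return(0)
  P <- Mod(stats::fft(x))^2
  half <- 2:(floor(n / 2) + 1L)          # exclude the zero-frequency bin
  freqs <- (half - 1L) / (n * dt)
  freqs[which.max(P[half])]
}

#' Area of the convex hull of a planar point set
#'
#' @param points Two-column matrix (or data frame) of coordinates.
#' @return Hull area (squared amplitude units); 0 for degenerate sets.
#' @export
hull_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) return(0)
  h <- grDevices::chull(points)
  v <- points[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Settling time onto a reference attractor
#'
#' First time after which the state stays within `tol` times the attractor
#' diameter of the reference point set. The reference defaults to the
#' trajectory's own final `attractor_window` time units; an independent
#' reference run can be supplied. The diameter is computed exactly from the
#' convex-hull vertices of the reference set.
#'
#' @param traj A [piezo_trajectory()].
#' @param reference Optional reference attractor: a [piezo_trajectory()] or a
#'   two-column matrix of `(z1, z2)` points.
#' @param tol Fractional tolerance (default 0.05 = 5% of attractor diameter).
#' @param attractor_window Length (time units) of the trailing window used
#'   when `reference` is NULL.
#' @return Settling time (dimensionless); `Inf` (with a warning) if the
#'   trajectory still exceeds the tolerance at its final sample.
#' @export
settling_time <- function(traj, reference = NULL, tol = 0.05,
                          attractor_window = 50) {
  if (is.null(reference)) {
    keep <- traj$tau >= traj$tau[nrow(traj)] - attractor_window
    ref <- cbind(traj$z1[keep], traj$z2[keep])
  } else if (inherits(reference, "piezo_trajectory")) {
    ref <- cbind(reference$z1, reference$z2)
  } else {
    ref <- as.matrix(reference)
  }
  hv <- ref[grDevices::chull(ref), , drop = FALSE]
  diam <- max(stats::dist(hv))
  if (diam == 0) stop("degenerate reference attractor (zero diameter)")
  thresh <- tol * diam
  d <- min_dist_to_set(cbind(traj$z1, traj$z2), ref)
  bad <- which(d > thresh)
  if (!length(bad)) return(traj$tau[1])
  if (max(bad) == nrow(traj)) {
    warning("trajectory does not settle within the run")
    return(Inf)
  }
  traj$tau[max(bad) + 1L]
}

# Chunked minimum Euclidean distance from each row of S to the point set P.
min_dist_to_set <- function(S, P, chunk = 2000L) {
  n <- nrow(S)
  out <- numeric(n)
  p1 <- P[, 1]; p2 <- P[, 2]
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D2 <- outer(S[s:e, 1], p1, "-")^2 + outer(S[s:e, 2], p2, "-")^2
    out[s:e] <- sqrt(apply(D2, 1, min))
  }
  out
}

#' Scalar features of an oscillatory trajectory
#'
#' Computes, on the post-transient segment: peak-to-peak energy amplitude;
#' coefficient of variation (percent) of successive energy-peak heights;
#' dominant frequency of `z1` (periodogram argmax, mean removed); convex-hull
#' area of the `(z1, z2)` phase points; and the settling time onto the
#' trajectory's own late-time attractor (computed on the full trajectory).
#'
#' @param traj A [piezo_trajectory()] on a uniform grid.
#' @param transient_cut Discard `tau < transient_cut` before feature
#'   extraction (default 100 time units).
#' @param prominence_frac Peak-detection prominence as a fraction of the
#'   energy peak-to-peak range (default 0.01).
#' @param settle_tol,attractor_window Passed to [settling_time()].
#' @param weights Energy weights, see [energy_series()].
#' @return An object of class `signal_features`: `peak_to_peak`,
#'   `cv_amplitude` (%), `n_peaks`, `dominant_freq` (cycles per unit time),
#'   `hull_area`, `settling_time`, plus the tuning values used.
#' @export
signal_features <- function(traj, transient_cut = 100, prominence_frac = 0.01,
                            settle_tol = 0.05, attractor_window = 50,
                            weights = c(0.5, 0.5)) {
  post <- cut_transient(traj, transient_cut)
  dt <- trajectory_dt(post)
  E <- energy_series(post, weights)
  p2p <- max(E) - min(E)
  # a circle orbit has constant energy but an oscillating state: treat energy
  # constancy (peak statistics) and state constancy (settling) separately
  e_constant <- p2p < 1e-12 * max(abs(E), 1)
  state_constant <- max(diff(range(post$z1)), diff(range(post$z2))) <
    1e-12 * max(abs(post$z1), abs(post$z2), 1)
  if (e_constant) {
    pk <- integer()
    cv <- 0
    p2p <- 0
  } else {
    pk <- find_peaks(E, prominence_frac * p2p)
    if (length(pk) < 2L)
      stop("fewer than 2 energy peaks after the transient cut; ",
           "cv_amplitude is undefined")
    if (length(pk) < 8L)
      warning("fewer than 8 energy peaks; cv_amplitude is poorly determined")
    cv <- 100 * stats::sd(E[pk]) / mean(E[pk])
  }
  structure(list(
    peak_to_peak = p2p,
    cv_amplitude = cv,
    n_peaks = length(pk),
    dominant_freq = dominant_frequency(post$z1, dt),
    hull_area = hull_area(cbind(post$z1, post$z2)),
    settling_time = if (state_constant) traj$tau[1] else
      settling_time(traj, tol = settle_tol,
                    attractor_window = attractor_window),
    transient_cut = transient_cut,
    prominence_frac = prominence_frac,
    settle_tol = settle_tol,
    weights = weights
  ), class = "signal_features")
}

#' @export
print.signal_features <- function(x, ...) {
  cat("signal_features\n")
  cat(sprintf("  energy peak-to-peak : %.4g\n", x$peak_to_peak))
  cat(sprintf("  peak CV             : %.3g%% (%d peaks)\n",
              x$cv_amplitude, x$n_peaks))
  cat(sprintf("  dominant frequency  : %.4g cycles/unit time\n",
              x$dominant_freq))
  cat(sprintf("  phase hull area     : %.4g\n", x$hull_area))
  cat(sprintf("  settling time       : %.4g (tol %g)\n",
              x$settling_time, x$settle_tol))
  invisible(x)
}
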