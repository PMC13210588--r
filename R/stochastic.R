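#' Pointwise ensemble statistics with a confidence band
#'
#' Pointwise mean and standard deviation of each component across the
#' ensemble, plus a normal-approximation confidence band for the ensemble
#' mean, `mean +/- z * sd / sqrt(n)`, and the time course of the `z1`
#' variance.
#'
#' @param run A [run_ensemble()] result with at least 2 members.
#' @param level Confidence level (default 0.95).
#' @return An object of class `ensemble_summary` with series `tau`,
#'   `mean_z1`, `mean_z2`, `sd_z1`, `sd_z2`, `ci_low_z1`, `ci_high_z1`,
#'   `ci_low_z2`, `ci_high_z2`, `var_z1`, and scalars `n_real`, `level`.
#' @export
ensemble_summary <- function(run, level = 0.95) {
  stopifnot(inherits(run, "piezo_ensemble"))
  n <- ncol(run$z1)
  if (n < 2L) stop("need at least 2 realizations")
  z <- stats::qnorm((1 + level) / 2)
  row_sd <- function(M) {
    mu <- rowMeans(M)
    sqrt(pmax(rowSums((M - mu)^2) / (ncol(M) - 1L), 0))
  }
  m1 <- rowMeans(run$z1); m2 <- rowMeans(run$z2)
  s1 <- row_sd(run$z1);   s2 <- row_sd(run$z2)
  structure(list(tau = run$tau,
                 mean_z1 = m1, mean_z2 = m2, sd_z1 = s1, sd_z2 = s2,
                 ci_low_z1 = m1 - z * s1 / sqrt(n),
                 ci_high_z1 = m1 + z * s1 / sqrt(n),
                 ci_low_z2 = m2 - z * s2 / sqrt(n),
                 ci_high_z2 = m2 + z * s2 / sqrt(n),
                 var_z1 = s1^2, n_real = n, level = level),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d realizations, %g%% confidence band\n",
              x$n_real, 100 * x$level))
  cat(sprintf("  mean CI half-width (z1): %.4g; max var(z1): %.4g\n",
              mean(x$ci_high_z1 - x$ci_low_z1) / 2, max(x$var_z1)))
  invisible(x)
}

#' Deviation of a stochastic ensemble from a deterministic path
#'
#' Per-component time series of the ensemble-mean absolute deviation from a
#' deterministic trajectory on the same grid, with time-averaged scalar
#' summaries. The fast variable carries the noise, so its deviation exceeds
#' the slow variable's for this model.
#'
#' @param det A deterministic [piezo_trajectory()] on the ensemble grid.
#' @param run A [run_ensemble()] result.
#' @return An object of class `det_stoch_comparison`: series `dev_z1`,
#'   `dev_z2` (mean member deviation), `mean_path_dev_z1`, `mean_path_dev_z2`
#'   (deviation of the ensemble mean), scalars `avg_dev_z1`, `avg_dev_z2`.
#' @export
compare_det_stoch <- function(det, run) {
  stopifnot(inherits(det, "piezo_trajectory"), inherits(run, "piezo_ensemble"))
  if (nrow(det) != length(run$tau) ||
      max(abs(det$tau - run$tau)) > 1e-9)
    stop("deterministic trajectory and ensemble must share the time grid")
  dev1 <- rowMeans(abs(run$z1 - det$z1))
  dev2 <- rowMeans(abs(run$z2 - det$z2))
  structure(list(tau = run$tau, dev_z1 = dev1, dev_z2 = dev2,
                 mean_path_dev_z1 = abs(rowMeans(run$z1) - det$z1),
                 mean_path_dev_z2 = abs(rowMeans(run$z2) - det$z2),
                 avg_dev_z1 = mean(dev1), avg_dev_z2 = mean(dev2)),
            class = "det_stoch_comparison")
}

#' @export
print.det_stoch_comparison <- function(x, ...) {
  cat("det_stoch_comparison\n")
  cat(sprintf("  time-averaged |deviation|: z1 = %.4g, z2 = %.4g\n",
              x$avg_dev_z1, x$avg_dev_z2))
  invisible(x)
}

#' Final-time distribution of an ensemble component
#'
#' Collects the final grid value of `z1` or `z2` across realizations, fits a
#' Gaussian by maximum likelihood (sample mean; sample standard deviation),
#' and bins the samples with the Freedman--Diaconis rule (a single bin when
#' the samples are degenerate).
#'
#' @param run A [run_ensemble()] result with >= 10 members.
#' @param component `"z1"` or `"z2"`.
#' @param det_ref Optional deterministic reference final value (the
#'   noise-free path's final value on the same grid).
#' @return An object of class `distribution_fit`: `samples`, `mu`, `sigma`,
#'   `breaks`, `counts`, `component`, `det_ref`.
#' @export
final_time_distribution <- function(run, component = c("z1", "z2"),
                                    det_ref = NULL) {
  stopifnot(inherits(run, "piezo_ensemble"))
  component <- match.arg(component)
  M <- run[[component]]
  if (ncol(M) < 10L) stop("need at least 10 realizations for a fit")
  s <- M[nrow(M), ]
  mu <- mean(s)
  sigma <- stats::sd(s)
  if (!is.finite(sigma)) sigma <- 0
  if (sigma == 0 || diff(range(s)) == 0) {
    breaks <- c(mu - 0.5, mu + 0.5)
    counts <- length(s)
  } else {
    bw <- 2 * stats::IQR(s) / length(s)^(1 / 3)
    if (bw <= 0) bw <- diff(range(s)) / ceiling(sqrt(length(s)))
    breaks <- seq(min(s), max(s) + bw, by = bw)
    counts <- as.integer(table(cut(s, breaks, include.lowest = TRUE,
                                   right = FALSE)))
  }
  structure(list(samples = s, mu = mu, sigma = sigma,
                 breaks = breaks, counts = counts,
                 component = component, det_ref = det_ref),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("distribution_fit (%s, n = %d): mu = %.4g, sigma = %.4g\n",
              x$component, length(x$samples), x$mu, x$sigma))
  if (!is.null(x$det_ref))
    cat(sprintf("  deterministic reference final value: %.4g\n", x$det_ref))
  invisible(x)
}

#' Spike times by upward threshold crossing
#'
#' Indices `i` with `x[i-1] < threshold <= x[i]`, thinned so that consecutive
#' spikes are at least `refractory` grid steps apart.
#'
#' @param x Signal series.
#' @param tau Matching time vector.
#' @param threshold Detection level.
#' @param refractory Minimum gap between spikes, in grid steps (default 2).
#' @return Numeric vector of spike times.
#' @export
spike_times <- function(x, tau, threshold, refractory = 2L) {
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  if (!length(up)) return(numeric())
  keep <- up[1]
  for (i in up[-1]) if (i - keep[length(keep)] >= refractory) keep <- c(keep, i)
  tau[keep]
}

#' Regularity of an inter-spike-interval sample
#'
#' The standard coherence statistic `R = mean(ISI) / sd(ISI)`: large for
#' regular (clock-like) firing, ~1 for Poisson firing, `Inf` for strictly
#' periodic trains.
#'
#' @param isi Vector of inter-spike intervals (needs >= 2).
#' @return `R`; `Inf` when `sd(isi) == 0`; `NA` when fewer than 2 intervals.
#' @export
isi_regularity <- function(isi) {
  if (length(isi) < 2L) return(NA_real_)
  s <- stats::sd(isi)
  if (s == 0) return(Inf)
  mean(isi) / s
}

#' Coherence-resonance noise sweep
#'
#' For each noise intensity, generates an ensemble of stochastic paths,
#' detects spikes of `z1` as upward threshold crossings (refractory gap of 2
#' grid steps), pools the inter-spike intervals across realizations and
#' reports the regularity `R = mean(ISI) / sd(ISI)`. The curve is returned as
#' measured: no claim is made that an interior maximum exists. Intensities
#' producing fewer than 3 spikes in total are flagged with `R = NA`.
#'
#' @inheritParams run_ensemble
#' @param sigmas Strictly increasing vector of noise intensities.
#' @param threshold Spike-detection level; default is the midpoint of the
#'   post-transient `z1` range of the noise-free path (transient = first half
#'   of the run).
#' @param n_real Realizations per intensity (default 10).
#' @return An object of class `coherence_scan`: data frame `curve` with
#'   columns `sigma`, `regularity`, `n_spikes`, plus `threshold` and
#'   `base_seed`. Seeds are blocked per intensity so members never collide.
#' @export
coherence_scan <- function(params, ic, grid = default_stoch_grid(),
                           sigmas, n_real = 10, base_seed = 42,
                           threshold = NULL) {
  if (!length(sigmas)) stop("sigmas must be non-empty")
  if (any(diff(sigmas) <= 0)) stop("sigmas must be strictly increasing")
  if (is.null(threshold)) {
    det <- euler_maruyama(piezo_params(psi = params$psi, eta = params$eta,
                                       a = params$a, lam = params$lam,
                                       A = params$A, Omega = params$Omega,
                                       sigma1 = 0),
                          ic, grid, seed = 0)
    post <- det$z1[det$tau >= (grid$t0 + grid$t1) / 2]
    threshold <- (max(post) + min(post)) / 2
  }
  reg <- numeric(length(sigmas))
  nsp <- integer(length(sigmas))
  for (si in seq_along(sigmas)) {
    p <- piezo_params(psi = params$psi, eta = params$eta, a = params$a,
                      lam = params$lam, A = params$A, Omega = params$Omega,
                      u_pc = params$u_pc, sigma1 = sigmas[si])
    run <- run_ensemble(p, ic, grid, n_real = n_real,
                        base_seed = base_seed + (si - 1L) * n_real)
    isis <- unlist(lapply(seq_len(n_real), function(i) {
      st <- spike_times(run$z1[, i], run$tau, threshold)
      if (length(st) >= 2L) diff(st) else numeric()
    }))
    nsp[si] <- sum(vapply(seq_len(n_real), function(i)
      length(spike_times(run$z1[, i], run$tau, threshold)), integer(1)))
    reg[si] <- if (nsp[si] < 3L) NA_real_ else isi_regularity(isis)
  }
  structure(list(curve = data.frame(sigma = sigmas, regularity = reg,
                                    n_spikes = nsp),
                 threshold = threshold, base_seed = base_seed,
                 n_real = n_real),
            class = "coherence_scan")
}

#' @export
print.coherence_scan <- function(x, ...) {
  cat(sprintf("coherence_scan: %d intensities, threshold = %.4g, %d paths each\n",
              nrow(x$curve), x$threshold, x$n_real))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
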