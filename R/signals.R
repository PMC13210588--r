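#' Synthetic test signals with known properties
#'
#' Fixture generators used to validate every analysis stage against
#' closed-form answers. Scalar signals carry their quadrature as the second
#' component, so `(z1, z2)` traces a known phase-space curve (a circle for a
#' pure sine) and the native m = 2 analysis paths are exercised without delay
#' embedding.
#'
#' `make_sine()`: `z1 = a sin(2 pi f tau + phi)`, `z2 = a cos(2 pi f tau + phi)`
#' (a perfect circle of radius `a`, hull area `pi a^2`).
#'
#' @param amplitude Amplitude `a`.
#' @param freq Frequency in cycles per unit time; must be below the grid
#'   Nyquist frequency `1 / (2 dt)`.
#' @param phase Phase offset (radians).
#' @param grid A [time_grid()].
#' @return A [piezo_trajectory()] with the generator settings in metadata.
#' @export
make_sine <- function(amplitude = 1, freq = 0.1, phase = 0,
                      grid = time_grid(0, 100, 2001)) {
  check_nyquist(freq, grid)
  ph <- 2 * pi * freq * grid$tau + phase
  piezo_trajectory(grid$tau, amplitude * sin(ph), amplitude * cos(ph),
                   meta = list(kind = "sine", amplitude = amplitude,
                               freq = freq, phase = phase))
}

#' @rdname make_sine
#' @details `make_two_tone()`: superposition of two sines (quadrature sum in
#'   `z2`). With incommensurate frequencies (e.g. `f2/f1` equal to the golden
#'   ratio) the trajectory is quasi-periodic and never exactly repeats.
#' @param a1,a2,f1,f2 Component amplitudes and frequencies (`f1 != f2`).
#' @export
make_two_tone <- function(a1 = 1, a2 = 1, f1 = 0.1, f2 = 0.1 * (1 + sqrt(5)) / 2,
                          grid = time_grid(0, 100, 2001)) {
  if (f1 == f2) stop("f1 and f2 must differ")
  check_nyquist(max(f1, f2), grid)
  w1 <- 2 * pi * f1 * grid$tau
  w2 <- 2 * pi * f2 * grid$tau
  piezo_trajectory(grid$tau,
                   a1 * sin(w1) + a2 * sin(w2),
                   a1 * cos(w1) + a2 * cos(w2),
                   meta = list(kind = "two_tone", a1 = a1, a2 = a2,
                               f1 = f1, f2 = f2))
}

#' @rdname make_sine
#' @details `make_white_noise()`: i.i.d. `N(0, noise_sd^2)` samples in both
#'   components (independent); bit-reproducible under a fixed seed.
#' @param noise_sd Standard deviation of the samples.
#' @param seed Integer seed (required: the fixture must be reproducible).
#' @export
make_white_noise <- function(noise_sd = 1, grid = time_grid(0, 100, 2001),
                             seed) {
  if (missing(seed)) stop("seed is required for stochastic fixtures")
  n <- grid$n_points
  z <- with_seed(as.integer(seed),
                 matrix(stats::rnorm(2L * n, 0, noise_sd), ncol = 2L))
  piezo_trajectory(grid$tau, z[, 1], z[, 2],
                   meta = list(kind = "white_noise", noise_sd = noise_sd,
                               seed = seed))
}

#' Synthetic spike train with controlled interval statistics
#'
#' Event times with either exponential inter-spike intervals (`rate` given:
#' Poisson firing, `mean(ISI) = sd(ISI) = 1/rate`) or fixed intervals with
#' fractional Gaussian jitter (`isi` given: `ISI_k = isi * (1 + jitter * e_k)`,
#' `e_k ~ N(0,1)`; `jitter = 0` is a strictly periodic clock).
#'
#' @param n Number of spikes.
#' @param rate Rate of the exponential ISI distribution (exclusive with `isi`).
#' @param isi Fixed base interval (exclusive with `rate`).
#' @param jitter Fractional standard deviation of the jittered intervals.
#' @param seed Integer seed (required unless the train is deterministic).
#' @return Numeric vector of event times (starting at the first interval).
#' @export
make_spike_train <- function(n, rate = NULL, isi = NULL, jitter = 0,
                             seed = NULL) {
  if (is.null(rate) == is.null(isi)) stop("give exactly one of rate or isi")
  stochastic <- !is.null(rate) || jitter > 0
  if (stochastic && is.null(seed)) stop("seed is required for stochastic fixtures")
  gaps <- if (!is.null(rate)) {
    with_seed(as.integer(seed), stats::rexp(n, rate))
  } else if (jitter > 0) {
    with_seed(as.integer(seed), isi * (1 + jitter * stats::rnorm(n)))
  } else {
    rep(isi, n)
  }
  if (any(gaps <= 0)) gaps <- pmax(gaps, 1e-9)  # jittered gap must stay positive
  cumsum(gaps)
}

check_nyquist <- function(freq, grid) {
  nyq <- 1 / (2 * grid$dt)
  if (freq >= nyq)
    stop("frequency ", freq, " is at or above the grid Nyquist limit ", nyq)
  invisible(TRUE)
}
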