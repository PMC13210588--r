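# Independent oracles used to check the package implementations.
# Deliberately written in the most naive style available: fixed-step RK4 with
# scalar state for the adaptive integrator, and explicit cell-walking loops
# for the recurrence-line statistics.

# Classical RK4 along the output grid `tau`, taking `substeps` internal steps
# per grid interval. `drift(t, y)` returns c(dz1, dz2).
oracle_rk4 <- function(drift, ic, tau, substeps = 16L) {
  n <- length(tau)
  out <- matrix(NA_real_, n, 2L)
  y <- as.numeric(ic[1:2])
  out[1, ] <- y
  for (i in seq_len(n - 1L)) {
    h <- (tau[i + 1L] - tau[i]) / substeps
    t <- tau[i]
    for (s in seq_len(substeps)) {
      k1 <- drift(t, y)
      k2 <- drift(t + h / 2, y + h / 2 * k1)
      k3 <- drift(t + h / 2, y + h / 2 * k2)
      k4 <- drift(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i + 1L, ] <- y
  }
  out
}

model_drift_fn <- function(params) {
  function(t, y) {
    c(y[1] * (1 - params$psi) - y[1]^3 / 3 - y[2] +
        params$A * cos(params$Omega * t),
      params$eta * (y[1] + params$a - params$lam * y[2]))
  }
}

# Brute-force recurrence quantification by exhaustive line enumeration.
oracle_rqa <- function(R, lmin = 2L, vmin = 2L) {
  n <- nrow(R)
  RR <- sum(R) / n^2
  diag_lens <- integer(0)
  for (off in c(-(n - 1L):-1L, 1L:(n - 1L))) {
    i <- max(1L, 1L - off)
    run <- 0L
    while (i <= n && i + off <= n && i + off >= 1L) {
      if (R[i, i + off]) {
        run <- run + 1L
      } else if (run > 0L) {
        diag_lens <- c(diag_lens, run)
        run <- 0L
      }
      i <- i + 1L
    }
    if (run > 0L) diag_lens <- c(diag_lens, run)
  }
  vert_lens <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (R[i, j]) {
        run <- run + 1L
      } else if (run > 0L) {
        vert_lens <- c(vert_lens, run)
        run <- 0L
      }
    }
    if (run > 0L) vert_lens <- c(vert_lens, run)
  }
  DET <- if (length(diag_lens)) {
    sum(diag_lens[diag_lens >= lmin]) / sum(diag_lens)
  } else 0
  LAM <- if (length(vert_lens)) {
    sum(vert_lens[vert_lens >= vmin]) / sum(vert_lens)
  } else 0
  keep <- diag_lens[diag_lens >= lmin]
  ENTR <- if (length(keep)) {
    p <- table(keep) / length(keep)
    -sum(p * log(p))
  } else 0
  list(RR = RR, DET = DET, LAM = LAM, ENTR = ENTR)
}

# Random symmetric binary matrix with an all-ones diagonal.
random_sym_R <- function(n, p, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n) < p, n, n)
  R <- M | t(M)
  diag(R) <- TRUE
  R
}

as_recurrence <- function(R) {
  structure(list(R = R, epsilon = NA_real_, metric = "given",
                 m = NA_integer_, delay_steps = NA_integer_, n = nrow(R)),
            class = "recurrence_matrix")
}

# Autonomous (A = 0, u_pc = 0) fixed point of the Set-1 constants, from the
# nullcline intersection f(z1) = z1(1 - psi) - z1^3/3 - (z1 + a)/lam = 0.
set1_fixed_point <- function(psi = 0.45, a = 0.4, lam = 0.18) {
  f <- function(z1) z1 * (1 - psi) - z1^3 / 3 - (z1 + a) / lam
  z1 <- stats::uniroot(f, c(-10, 10), tol = 1e-14)$root
  c(z1 = z1, z2 = (z1 + a) / lam)
}

# Hand-built ensemble of constant paths with i.i.d. per-member levels.
const_ensemble <- function(levels, tau = seq(0, 1, length.out = 11)) {
  n <- length(tau)
  m <- length(levels)
  structure(list(tau = tau,
                 z1 = matrix(rep(levels, each = n), n, m),
                 z2 = matrix(0, n, m),
                 seeds = seq_len(m), sigma1 = NA_real_,
                 params = list(), ic = c(0, 0), dt = tau[2] - tau[1]),
            class = "piezo_ensemble")
}
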