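#' Delay embedding of a scalar series
#'
#' Rows are the m-dimensional delay vectors
#' `(x_i, x_{i+d}, ..., x_{i+(m-1)d})`; the output has
#' `length(x) - (m-1) * delay_steps` rows. For the native model state no
#' embedding is needed: [recurrence_matrix()] uses the `(z1, z2)` columns
#' directly when given a trajectory.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (>= 1).
#' @param delay_steps Embedding delay in grid steps (>= 1).
#' @return Matrix of embedded points (rows).
#' @export
embed_series <- function(x, m = 2, delay_steps = 1) {
  m <- as.integer(m); delay_steps <- as.integer(delay_steps)
  if (m < 1L || delay_steps < 1L) stop("m and delay_steps must be >= 1")
  n_pts <- length(x) - (m - 1L) * delay_steps
  if (n_pts < 1L) stop("series too short for this embedding")
  out <- matrix(NA_real_, n_pts, m)
  for (j in seq_len(m)) out[, j] <- x[seq_len(n_pts) + (j - 1L) * delay_steps]
  out
}

#' Recurrence matrix of a point sequence
#'
#' Thresholded pairwise distances: `R[i, j] = 1` iff `d(p_i, p_j) <= epsilon`.
#' The default metric is the cosine distance
#' `d = 1 - <p_i, p_j> / (|p_i| |p_j|)`, which compares phase-space direction
#' and ignores magnitude; Euclidean distance is also available. Points with
#' norm below 1e-12 have no defined direction: they are set non-recurrent
#' with every other point (distance 1) with a warning, but remain recurrent
#' with themselves, so the diagonal is all ones.
#'
#' @param x A [piezo_trajectory()] (native `(z1, z2)` state, m = 2), a numeric
#'   matrix of points (rows), or a scalar series (delay-embedded with
#'   `m`, `delay_steps`).
#' @param epsilon Recurrence threshold (> 0); default 0.05.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param m,delay_steps Embedding settings for scalar input (defaults 2 and 1,
#'   i.e. a delay of one grid step).
#' @return An object of class `recurrence_matrix`: logical matrix `R`,
#'   `epsilon`, `metric`, `m`, `delay_steps`, `n`.
#' @export
recurrence_matrix <- function(x, epsilon = 0.05,
                              metric = c("cosine", "euclidean"),
                              m = 2, delay_steps = 1) {
  metric <- match.arg(metric)
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (inherits(x, "piezo_trajectory")) {
    pts <- cbind(x$z1, x$z2)
    m <- 2L; delay_steps <- 0L
  } else if (is.matrix(x)) {
    pts <- x
    m <- ncol(x); delay_steps <- 0L
  } else {
    pts <- embed_series(as.numeric(x), m, delay_steps)
  }
  if (!all(is.finite(pts))) stop("points must be finite")
  n <- nrow(pts)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(pts^2))
    degen <- nrm < 1e-12
    nrm[degen] <- 1
    U <- pts / nrm
    D <- 1 - tcrossprod(U)
    if (any(degen)) {
      warning(sum(degen), " zero-norm point(s): set non-recurrent ",
              "(cosine direction undefined)")
      D[degen, ] <- 1
      D[, degen] <- 1
    }
  } else {
    G <- tcrossprod(pts)
    sq <- rowSums(pts^2)
    D2 <- outer(sq, sq, "+") - 2 * G
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
  }
  R <- D <= epsilon
  diag(R) <- TRUE
  structure(list(R = R, epsilon = epsilon, metric = metric,
                 m = as.integer(m), delay_steps = as.integer(delay_steps),
                 n = n),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("recurrence_matrix: %d x %d, %s distance, epsilon = %g\n",
              x$n, x$n, x$metric, x$epsilon))
  cat(sprintf("  density (incl. identity line): %.4f\n", mean(x$R)))
  invisible(x)
}

# Histogram of diagonal line lengths, LOI excluded, both triangles counted
# (hist[l] = number of diagonal lines of exactly length l).
diag_line_hist <- function(R) {
  n <- nrow(R)
  hist <- integer(n)
  for (k in seq_len(n - 1L)) {
    i <- seq_len(n - k)
    d <- R[cbind(i, i + k)]
    r <- rle(d)
    lens <- r$lengths[r$values]
    if (length(lens)) {
      t <- tabulate(lens, nbins = n)
      hist <- hist + t
    }
  }
  2L * hist
}

# Histogram of vertical line lengths over the full matrix (LOI included,
# standard practice for laminarity).
vert_line_hist <- function(R) {
  n <- nrow(R)
  hist <- integer(n)
  for (j in seq_len(n)) {
    r <- rle(R[, j])
    lens <- r$lengths[r$values]
    if (length(lens)) hist <- hist + tabulate(lens, nbins = n)
  }
  hist
}

#' Recurrence quantification measures
#'
#' From a [recurrence_matrix()], computes:
#' \describe{
#'   \item{RR}{recurrence rate, the density of recurrent cells over the full
#'     matrix (identity line included).}
#'   \item{DET}{determinism, the fraction of diagonal-line recurrence points
#'     lying on diagonal lines of length >= `lmin`, with the line of identity
#'     excluded from all diagonal statistics.}
#'   \item{LAM}{laminarity, the vertical-line analogue (full matrix), with
#'     minimum length `vmin`.}
#'   \item{ENTR}{Shannon entropy (nats) of the distribution of diagonal line
#'     lengths >= `lmin`.}
#' }
#' When no qualifying lines exist the affected measure is reported as 0 and
#' flagged via `det_defined` / `lam_defined`.
#'
#' @param rm A [recurrence_matrix()].
#' @param lmin Minimum diagonal line length (default 2).
#' @param vmin Minimum vertical line length (default 2).
#' @return An object of class `rqa_measures`.
#' @export
rqa <- function(rm, lmin = 2, vmin = 2) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  R <- rm$R
  n <- rm$n
  RR <- sum(R) / n^2
  dh <- diag_line_hist(R)
  lv <- seq_len(n)
  tot_d <- sum(lv * dh)
  det_defined <- tot_d > 0
  DET <- if (det_defined) sum(lv[lv >= lmin] * dh[lv >= lmin]) / tot_d else 0
  vh <- vert_line_hist(R)
  tot_v <- sum(lv * vh)
  lam_defined <- tot_v > 0
  LAM <- if (lam_defined) sum(lv[lv >= vmin] * vh[lv >= vmin]) / tot_v else 0
  dl <- dh[lv >= lmin]
  ENTR <- if (sum(dl) > 0) {
    p <- dl[dl > 0] / sum(dl)
    -sum(p * log(p))
  } else 0
  structure(list(RR = RR, DET = DET, LAM = LAM, ENTR = ENTR,
                 lmin = as.integer(lmin), vmin = as.integer(vmin),
                 n = n, det_defined = det_defined,
                 lam_defined = lam_defined),
            class = "rqa_measures")
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf("rqa_measures (n = %d, lmin = %d, vmin = %d)\n",
              x$n, x$lmin, x$vmin))
  cat(sprintf("  RR   = %.4f\n  DET  = %.4f%s\n  LAM  = %.4f%s\n  ENTR = %.4f nats\n",
              x$RR, x$DET, if (x$det_defined) "" else " (no lines)",
              x$LAM, if (x$lam_defined) "" else " (no lines)",
              x$ENTR))
  invisible(x)
}
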