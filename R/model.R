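#' Right-hand sides of the oscillator
#'
#' `rhs_autonomous()` is the constant-stimulation variant
#' (`psi * u_pc` drive); `rhs_forced()` replaces that term with the harmonic
#' forcing `A * cos(Omega * tau)`. The slow equation
#' `dz2 = eta * (z1 + a - lam * z2)` is shared. Both are total functions on
#' finite states and are the single source of the drift used by every
#' integrator in the package.
#'
#' @param state Numeric vector `c(z1, z2)` (finite).
#' @param tau Dimensionless time (forced variant only).
#' @param params A [piezo_params()] object.
#' @return Named numeric vector `c(dz1, dz2)`.
#' @examples
#' p <- param_set("set1")
#' rhs_forced(initial_condition("ic1"), 0, p)
#' @export
rhs_forced <- function(state, tau, params) {
  z1 <- state[[1]]; z2 <- state[[2]]
  c(dz1 = z1 * (1 - params$psi) - z1^3 / 3 - z2 +
          params$A * cos(params$Omega * tau),
    dz2 = params$eta * (z1 + params$a - params$lam * z2))
}

#' @rdname rhs_forced
#' @export
rhs_autonomous <- function(state, params) {
  z1 <- state[[1]]; z2 <- state[[2]]
  c(dz1 = z1 * (1 - params$psi) - z1^3 / 3 - z2 + params$psi * params$u_pc,
    dz2 = params$eta * (z1 + params$a - params$lam * z2))
}

# Vectorized drift used by the basin mapper and the stochastic stepper:
# takes z1, z2 (equal-length vectors) and scalar tau, returns list(dz1, dz2).
model_drift <- function(params) {
  force(params)
  function(z1, z2, tau) {
    list(dz1 = z1 * (1 - params$psi) - z1^3 / 3 - z2 +
               params$A * cos(params$Omega * tau),
         dz2 = params$eta * (z1 + params$a - params$lam * z2))
  }
}
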