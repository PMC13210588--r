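#' Dimensionless model parameters
#'
#' Constructs the parameter object for the dimensionless piezoelectric neuron
#' oscillator. The fast variable obeys
#' \deqn{\dot z_1 = z_1(1-\psi) - z_1^3/3 - z_2 + A\cos(\Omega\tau)}
#' and the slow variable \deqn{\dot z_2 = \eta (z_1 + a - \lambda z_2).}
#' With `A = 0` the constant-stimulation variant uses `psi * u_pc` in place of
#' the harmonic forcing. `sigma1` is the intensity of additive Gaussian white
#' noise on `z1` used by the stochastic integrator.
#'
#' @param psi Coupling ratio \eqn{\psi = \rho/R_s} (dimensionless).
#' @param eta Time-scale separation \eqn{\eta = \rho^2 C/L} (> 0).
#' @param a Reversal-potential ratio \eqn{a = E/V_0}.
#' @param lam Resistance ratio \eqn{\lambda = R/\rho} (> 0).
#' @param A Forcing amplitude (>= 0).
#' @param Omega Angular forcing frequency (rad per unit dimensionless time).
#' @param u_pc Constant external stimulation (dimensionless; default 0).
#' @param sigma1 Noise intensity on `z1` (>= 0).
#' @return An object of class `piezo_params` (a named list).
#' @seealso [param_set()] for the shipped presets.
#' @examples
#' p <- piezo_params(A = 0.75, Omega = 1.2)
#' rhs_forced(c(z1 = 0, z2 = 0), 0, p)
#' @export
piezo_params <- function(psi = 0.45, eta = 0.12, a = 0.4, lam = 0.18,
                         A = 0, Omega = 0, u_pc = 0, sigma1 = 0) {
  p <- list(psi = psi, eta = eta, a = a, lam = lam,
            A = A, Omega = Omega, u_pc = u_pc, sigma1 = sigma1)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (eta <= 0) stop("eta must be > 0")
  if (lam <= 0) stop("lam must be > 0")
  if (sigma1 < 0) stop("sigma1 must be >= 0")
  if (A < 0) stop("A must be >= 0")
  structure(p, class = "piezo_params")
}

#' @export
print.piezo_params <- function(x, ...) {
  cat("Piezoelectric neuron parameters\n")
  cat(sprintf("  psi = %g, eta = %g, a = %g, lambda = %g\n",
              x$psi, x$eta, x$a, x$lam))
  cat(sprintf("  forcing: A = %g, Omega = %g (u_pc = %g)\n", x$A, x$Omega, x$u_pc))
  cat(sprintf("  noise:   sigma1 = %g\n", x$sigma1))
  invisible(x)
}

#' Shipped parameter-set and initial-condition presets
#'
#' Three forcing regimes sharing the baseline constants `psi = 0.45`,
#' `eta = 0.12`, `a = 0.4`, `lam = 0.18`:
#' `set1` (A = 0.75, Omega = 1.2; low amplitude, low frequency),
#' `set2` (A = 0.85, Omega = 1.6; moderate) and
#' `set3` (A = 1.3, Omega = 1.9; strong, high frequency).
#'
#' @param name `"set1"`, `"set2"` or `"set3"`.
#' @param sigma1 Optional noise intensity carried into the preset.
#' @return A [piezo_params()] object.
#' @export
param_set <- function(name = c("set1", "set2", "set3"), sigma1 = 0) {
  name <- match.arg(name)
  f <- switch(name,
    set1 = c(A = 0.75, Omega = 1.2),
    set2 = c(A = 0.85, Omega = 1.6),
    set3 = c(A = 1.3,  Omega = 1.9))
  piezo_params(A = f[["A"]], Omega = f[["Omega"]], sigma1 = sigma1)
}

#' @rdname param_set
#' @details The three initial conditions probe increasing displacement from
#'   equilibrium: `ic1 = (0.05, -0.03)` (near-equilibrium), `ic2 = (0.8, 0.2)`
#'   (moderately displaced) and `ic3 = (-1.2, 1.6)` (strongly perturbed).
#' @return For `initial_condition()`, a named numeric vector `c(z1, z2)`.
#' @export
initial_condition <- function(name = c("ic1", "ic2", "ic3")) {
  name <- match.arg(name)
  switch(name,
    ic1 = c(z1 = 0.05, z2 = -0.03),
    ic2 = c(z1 = 0.8,  z2 = 0.2),
    ic3 = c(z1 = -1.2, z2 = 1.6))
}

#' Physical circuit parameters
#'
#' Optional description of the physical piezoelectric neuron circuit from which
#' the dimensionless constants derive. All analyses run on dimensionless
#' parameters; this type exists for unit conversion and documentation of a
#' concrete device.
#'
#' @param F_force External mechanical force (N).
#' @param S Cross-sectional area (m^2).
#' @param d33 Piezoelectric strain constant (C/N).
#' @param eps_diel Dielectric constant (F/m).
#' @param h Device thickness (m).
#' @param Q Released charge (C); if given, must satisfy `d33 = Q/F_force`.
#' @param C_cap Capacitance (F).
#' @param L_ind Inductance (H).
#' @param Rs,R_lin Series and linear resistances (Ohm).
#' @param E_src Reversal-potential source (V); any sign.
#' @param V0 Cutoff voltage of the nonlinear resistor (V).
#' @param rho Normalization resistance (Ohm).
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(F_force, S, d33, eps_diel, h, Q = NULL,
                            C_cap, L_ind, Rs, R_lin, E_src, V0, rho) {
  p <- list(F_force = F_force, S = S, d33 = d33, eps_diel = eps_diel, h = h,
            Q = Q, C_cap = C_cap, L_ind = L_ind, Rs = Rs, R_lin = R_lin,
            E_src = E_src, V0 = V0, rho = rho)
  pos <- setdiff(names(p), c("E_src", "Q"))
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number")
  }
  if (!is.null(Q)) {
    if (abs(d33 - Q / F_force) > 1e-12 * max(abs(d33), 1))
      stop("inconsistent charge: d33 must equal Q/F_force")
  }
  structure(p, class = "physical_params")
}

#' Piezoelectric open-circuit voltage
#'
#' Voltage generated across a piezoelectric element of thickness `h` under
#' pressure `F_force/S`: `V = (F/S) * (d33/eps_diel) * h`. Linear in the force
#' and in the thickness.
#'
#' @inheritParams physical_params
#' @return Voltage (V).
#' @examples
#' piezo_voltage(1, 1, 1, 1, 1)  # 1
#' @export
piezo_voltage <- function(F_force, S, d33, eps_diel, h) {
  if (S <= 0) stop("S must be > 0")
  if (eps_diel <= 0) stop("eps_diel must be > 0")
  (F_force / S) * (d33 / eps_diel) * h
}

#' Current through the cubic nonlinear resistor
#'
#' `I = -(1/rho) * (V - V^3 / (3 V0^2))`: the N-shaped (cubic) current-voltage
#' law responsible for the excitable dynamics. Odd in `V`; roots at
#' `V = 0` and `V = +/- sqrt(3) V0`.
#'
#' @param V Voltage across the resistor (V).
#' @param V0 Cutoff voltage (V, nonzero).
#' @param rho Normalization resistance (Ohm, > 0).
#' @return Current (A).
#' @export
nonlinear_resistor_current <- function(V, V0, rho) {
  if (rho <= 0) stop("rho must be > 0")
  if (V0 == 0) stop("V0 must be nonzero")
  -(1 / rho) * (V - V^3 / (3 * V0^2))
}

#' Dimensionless constants from a physical circuit
#'
#' Applies the defining ratios `psi = rho/Rs`, `a = E/V0`, `lam = R/rho`,
#' `eta = rho^2 C / L`. Forcing and noise are not determined by the circuit
#' constants and default to zero in the result.
#'
#' @param p A [physical_params()] object.
#' @return A [piezo_params()] object with `A = Omega = u_pc = sigma1 = 0`.
#' @export
dimensionless_from_physical <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  piezo_params(psi = p$rho / p$Rs,
               a = p$E_src / p$V0,
               lam = p$R_lin / p$rho,
               eta = p$rho^2 * p$C_cap / p$L_ind)
}
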