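---
title: "Methods: deterministic and stochastic analysis of the piezoelectric neuron oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic and stochastic analysis of the piezoelectric neuron oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezoneuron)
```

## The model

The package studies a FitzHugh–Nagumo-type fast–slow oscillator describing a
piezoelectric neuron circuit: a piezoelectric element converts mechanical
stress into a driving voltage feeding a nonlinear (cubic-resistor) circuit
whose capacitor voltage and inductor current behave like the activation and
recovery variables of an excitable cell. In dimensionless form,

$$\dot z_1 = z_1(1-\psi) - \tfrac{1}{3}z_1^3 - z_2 + A\cos(\Omega\tau),
\qquad
\dot z_2 = \eta\,(z_1 + a - \lambda z_2),$$

where $z_1$ is the fast activation variable (capacitor voltage over the
cutoff voltage $V_0$), $z_2$ the slow recovery variable (scaled inductor
current), and $\tau$ dimensionless time. The constants derive from circuit
ratios: $\psi = \rho/R_s$, $a = E/V_0$, $\lambda = R/\rho$,
$\eta = \rho^2 C/L$ ([`dimensionless_from_physical()`]); $\eta \ll 1$
enforces the time-scale separation. The constant-stimulation variant
(`rhs_autonomous()`, drive $\psi\,u_{PC}$) is exposed for completeness, but
every shipped preset uses the harmonic forcing, so the forced field is the
default throughout; `u_pc` defaults to 0 because no reference configuration
prescribes a constant-drive value.

The stochastic extension adds additive Gaussian white noise of intensity
$\sigma_1$ to the fast equation only,

$$dz_1 = \big[z_1(1-\psi) - \tfrac{1}{3}z_1^3 - z_2 + A\cos(\Omega\tau)\big]d\tau
+ \sigma_1\,dW_1(\tau),$$

modelling environmental fluctuation acting on the fast output; the slow
subsystem filters high-frequency noise and is integrated deterministically
within each step. An exploratory switch adds noise on $z_2$, but it is off by
default and excluded from all reference analyses.

## Reference configuration

All analyses share baseline constants $\psi=0.45$, $\eta=0.12$, $a=0.4$,
$\lambda=0.18$. Three forcing regimes are shipped as presets
(`param_set()`): Set 1 ($A=0.75$, $\Omega=1.2$), Set 2 ($A=0.85$,
$\Omega=1.6$), Set 3 ($A=1.3$, $\Omega=1.9$); and three initial conditions
(`initial_condition()`): near-equilibrium $(0.05,-0.03)$, moderately
displaced $(0.8,0.2)$, strongly perturbed $(-1.2,1.6)$.

Deterministic runs use LSODA (adaptive step, automatic stiff/non-stiff
switching, via **deSolve**) sampled on 20,000 equally spaced points over
$\tau\in[0,300]$ ($\Delta\tau\approx0.015$). The solver's "default"
tolerances are pinned to `rtol = atol = 1.49e-8` and recorded in every
trajectory's metadata: reproducibility requires explicit values, and these
are the conventional defaults of widely used adaptive solvers. Stochastic
runs use Euler–Maruyama with 5,000 steps on $\tau\in[0,100]$
($\Delta\tau=0.02$), $\sigma_1 = 0.1$ and base seed 42; the output grid *is*
the stepping grid, because an Euler–Maruyama path is defined only at its step
points. Ensemble member $i$ is seeded `base_seed + i - 1` with its own
generator state, so ensembles are order-independent and each member can be
regenerated in isolation. Because the noise is additive, Euler–Maruyama here
converges strongly at order 1 (it coincides with Milstein); the test suite
checks that halving the step roughly halves the strong endpoint error.

No reference protocol states whether a transient is discarded before
analysis, so every analysis takes an explicit `transient_cut` argument
(default 100 time units) instead of hiding the choice.

## Analysis stages and their numerical choices

**Energy and signal features.** No energy functional is printed for this
model; the package fixes the simplest quadratic storage function
$E = \tfrac12(z_1^2+z_2^2)$ and exposes the weights. Regularity is
summarised by the coefficient of variation of successive energy-peak
heights, which is scale-free and therefore insensitive to the weighting.
Peaks are strict 3-point maxima filtered by a prominence of 1% of the energy
peak-to-peak range, suppressing float-noise double peaks. The dominant
frequency is the periodogram argmax of mean-removed $z_1$; the phase-space
"area" is the convex-hull area of the post-transient $(z_1,z_2)$ points —
deterministic and parameter-free, though it overestimates the area of
annular attractors (it fills the hole). Settling time is the first $\tau$
after which the state stays within 5% of the attractor diameter of a
reference point set (by default the trajectory's own final 50 time units);
the diameter is computed exactly from the hull vertices, and the tolerance
is recorded in the output.

**Basins of attraction.** A 300×300 grid of initial conditions on
$[-2,2]^2$ is integrated with fixed-step RK4 at $dt=0.05$ to horizon
$T=100$ (no scheme is named in the reference protocol; fixed-step RK4 has
deterministic per-node cost and is accurate at this step for this smooth
flow). All nodes are advanced simultaneously as vectors, which is what makes
the full grid affordable. Following the stated classifier literally, the
*sign of $z_1$ at the final time* labels each node (+1/−1, with
$|z_1(T)| \le$ `label_tol` mapped to 0) even though the asymptotic states of
the forced system are oscillatory, so the label records the oscillation
phase at the horizon rather than membership of distinct point attractors.
Trajectories exceeding $|z|>10^6$ are frozen, labelled 0 and counted.

**Sensitivity.** A perturbation $\delta$ (default 0.01; no magnitude is
prescribed) is applied to the initial $z_1$ and $|\Delta z_1(\tau)|$ is
tracked; the summary records the peak divergence and the residual (mean over
the final 10%), whose ordering demonstrates transient sensitivity followed
by reconvergence onto the shared attractor.

**Return maps.** Pairs $(z_1(\tau), z_1(\tau+\zeta))$ with $\zeta$ rounded
to a whole number of grid steps (the realized delay is reported). The twelve
default delays are $\zeta_j = j\,(2\pi/\Omega)/6$, $j=1..12$ — two forcing
periods in sixths — since no explicit delay list is prescribed.

**Recurrence quantification.** The native $(z_1,z_2)$ state serves as the
embedded point ($m=2$ equals the system dimension; scalar signals use delay
embedding with a default delay of one grid step). Distances are cosine
($d = 1 - \cos\angle$) on the raw states — cosine is scale-invariant per
point, so no normalization is applied — with threshold $\varepsilon=0.05$.
Points with norm below $10^{-12}$ have no direction and are set
non-recurrent with a warning (the attractor is offset from the origin, so
this path is rare). RR counts the full matrix including the identity line,
matching the "density of recurrence points" definition; DET and ENTR use
diagonal lines of length $\ge l_{\min}=2$ with the identity line excluded
(standard practice; the reference text is silent), and LAM uses vertical
lines of length $\ge v_{\min}=2$ over the full matrix. Full 20,000-point
runs would need $4\times10^8$ matrix cells, so pipelines downsample
post-transient trajectories to 2,000 points by uniform stride (recorded in
metadata). The implementation is validated cell-for-cell against an
exhaustive line-enumeration oracle on random symmetric matrices up to
$n=64$.

**Ensemble statistics.** Pointwise mean and standard deviation with a
normal-approximation 95% band for the ensemble mean,
$\bar z \pm z_{0.975}\,s/\sqrt{n}$ (no interval method is prescribed; the
normal band is the simplest defensible choice at $n=50$). The
deterministic-vs-stochastic comparison re-integrates the deterministic path
on the stochastic grid and reports mean absolute deviations per component.
Final-time distributions fit a Gaussian by maximum likelihood (sample mean,
sample standard deviation) with Freedman–Diaconis histogram bins; the
"deterministic reference" marked in the output is the $\sigma_1=0$ path's
final value on the same grid.

**Coherence scan.** No noise grid, regularity measure or numbers are
prescribed for the coherence-resonance observation, so this stage is a
faithful but parameterized reconstruction: spikes are upward threshold
crossings of $z_1$ (threshold defaulting to the midpoint of the noise-free
post-transient range, refractory gap 2 grid steps), inter-spike intervals
are pooled across realizations (recorded), and regularity is
$R = \overline{\mathrm{ISI}}/\mathrm{sd}(\mathrm{ISI})$ — the standard
coherence-resonance statistic ($R\to\infty$ for a clock, $R\approx1$ for
Poisson firing). The curve is returned as measured; the package makes no
claim that an interior maximum exists.

## Synthetic test signals

Every analysis stage is testable without the model through generators with
closed-form answers: a sine with its cosine quadrature (a perfect circle —
known hull area $\pi a^2$, known dominant frequency, zero energy
variation), a two-tone signal with incommensurate frequencies (golden-ratio
default) emulating quasi-periodic structure, Gaussian white noise, and spike
trains with exponential or jittered-clock intervals. The quadrature second
component exists so that the native two-dimensional analysis path is
exercised without delay embedding. All stochastic fixtures require a seed
and are bit-reproducible. These fixtures emulate the *geometry* the analyses
must resolve, not the neuron model itself: passing them shows the machinery
is correct, not that real sensor data would behave like the model.

## What the pipeline writes

`run_pipeline()` consumes a configuration list (or JSON file; JSON was
chosen as the config format because it round-trips through the same
serializer as every other artifact) merged over `pipeline_config()`, and
writes plain-text artifacts only: full-precision CSV (17 significant
digits, so write-then-read is exact), JSON sidecars for metadata, optional
ASCII PGM images. Every stochastic artifact records its seeds, making
output directories bit-reproducible from their config snapshot. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`; the exported
functions are the primary interface.

## Scale choices and known limitations

Test and example runs use reduced problem sizes chosen to exercise the same
code paths at desk scale: basin grids of 21–59 nodes (the full 300×300 map
is a single vectorized call away), recurrence matrices of 300–2,000 points,
ensembles of 3–50 members. The strong-convergence and Wiener-variance
properties of the stochastic stepper are checked on an injectable-drift
harness (`em_path()`), so closed-form expectations apply to the exact
stepper used for the model.

Under the printed Set-1 forcing the model settles onto a quasi-periodic
torus (incommensurate forcing and natural frequencies), not a phase-locked
limit cycle. Three documented consequences, all computed honestly by the
package rather than adjusted away: successive energy peaks are strongly
modulated by the beat between the two frequencies, so their CV is large
(~60%, stable under grid refinement and confirmed by an independent
fixed-step integration); cosine recurrence at $\varepsilon=0.05$ marks only
phase-aligned state pairs, giving RR ≈ 0.21 for Set 1; and a trajectory
started elsewhere on the torus keeps drifting through torus phases not
covered by a 50-time-unit reference window, so the 5% settling criterion can
exceed 50 time units for the moderately displaced initial condition. The
determinism (DET) of all three regimes is robustly high, as expected for
structured quasi-periodic motion.

Out of scope by design: circuit-level (SPICE-style) simulation of the
physical schematic, Lyapunov exponents, bifurcation sweeps, colored or
multiplicative noise, higher-order SDE schemes, and any plotting beyond the
PGM dumps — figures belong downstream of the exported data.
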