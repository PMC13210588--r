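# piezoneuron

Simulation and analysis of a **piezoelectric neuron oscillator**: a
FitzHugh–Nagumo-type fast–slow excitable circuit in which a piezoelectric
element converts mechanical stress into a driving voltage. The package is
aimed at researchers in nonlinear dynamics and neuromorphic sensing who want
a reproducible, fully scripted account of the model's deterministic geometry
and its behaviour under noise.

The dimensionless model is

$$\dot z_1 = z_1(1-\psi) - \tfrac{1}{3}z_1^3 - z_2 + A\cos(\Omega\tau),
\qquad
\dot z_2 = \eta\,(z_1 + a - \lambda z_2),$$

with fast activation $z_1$, slow recovery $z_2$, circuit-ratio constants
$\psi, a, \lambda, \eta$ and harmonic forcing $(A, \Omega)$. The stochastic
extension adds additive Gaussian white noise $\sigma_1\,dW_1$ on the fast
variable and is integrated with Euler–Maruyama under seed control.

Provided analyses:

- **Trajectories** — adaptive LSODA integration and seed-controlled
  Euler–Maruyama ensembles (`integrate_deterministic`, `euler_maruyama`,
  `run_ensemble`);
- **Phase geometry** — energy/feature extraction, settling times,
  300×300 basin-of-attraction maps (vectorized fixed-step RK4), sensitivity
  to initial perturbations, delay return maps;
- **Recurrence quantification** — cosine-distance recurrence plots and
  RR/DET/LAM/ENTR, validated against an exhaustive line-enumeration oracle;
- **Ensemble statistics** — mean/95% band/variance evolution,
  deterministic-vs-stochastic comparison, final-time Gaussian fits, and a
  coherence-resonance noise sweep (ISI regularity $R$ = mean/sd);
- **Synthetic signals** — sines, incommensurate two-tone signals, white
  noise and spike trains with known answers, so every stage is testable;
- **Pipeline** — `run_pipeline()` drives all stages from a JSON/list config
  into a self-describing directory of plain-text artifacts (CSV/JSON/PGM).

## Worked example

```r
library(piezoneuron)

# Forcing regime Set 1 (A = 0.75, Omega = 1.2) from the near-equilibrium
# initial condition, 20,000 points on tau in [0, 300]:
tr <- integrate_deterministic(param_set("set1"), initial_condition("ic1"))
signal_features(tr, transient_cut = 100)
#> signal_features
#>   energy peak-to-peak : 1.474
#>   peak CV             : 60.7% (52 peaks)
#>   dominant frequency  : 0.05 cycles/unit time
#>   phase hull area     : 2.575
#>   settling time       : 0 (tol 0.05)

post <- downsample_trajectory(cut_transient(tr, 100), 500)
rqa(recurrence_matrix(post, epsilon = 0.05, metric = "cosine"))
#> rqa_measures (n = 500, lmin = 2, vmin = 2)
#>   RR   = 0.2094
#>   DET  = 0.9645
#>   LAM  = 0.9720
#>   ENTR = 2.4594 nats
```

The feature block says the post-transient motion is bounded and
quasi-periodic: the energy oscillates with a beat-modulated envelope (hence
the large peak CV), the dominant spectral line of `z1` sits at 0.05 cycles
per unit time, and the near-equilibrium start is already on the attractor
(settling time 0). The recurrence block quantifies the same structure:
high determinism (DET ≈ 0.96 — recurrences organise into diagonal lines,
as for structured, non-chaotic motion) at a moderate recurrence density
under the strict cosine threshold ε = 0.05.

A stochastic ensemble and its statistics:

```r
p <- param_set("set1", sigma1 = 0.1)
run <- run_ensemble(p, initial_condition("ic1"), n_real = 50, base_seed = 42)
s <- ensemble_summary(run)          # mean, sd, 95% band, variance evolution
d <- final_time_distribution(run, "z1")
```

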