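# healthmarket

A deterministic, seeded multi-agent simulator of healthcare markets,
written for health economists and policy modellers who want to study how
dynamic pricing, adaptive insurance premiums, targeted incentives and
subsidy/tax policy interact — plus a cohort summarizer for per-patient
economic outcome tables of the kind produced when comparing AI-assisted
care management against standard care.

## The model

Four kinds of agents are coupled into one dynamical system:

* **Consumers** maximize quadratic utility
  `U(q, y) = a q − (b/2) q² + c y`, giving the consumption rule
  `q* = max(0, (a − λ(p + ṗ))/b)`. Insurance coverage `α` induces moral
  hazard through `U′(q′) = α U′(q*)`; subsidies act via the effective
  price `p′ = p − T(q)`.
* **Providers** supply `q = max(0, (p − c₁)/(2c₂))` from the convex
  cost `C(q) = c₀ + c₁q + c₂q²`; markets clear by bisection on
  `D(p) = S(p)`.
* **The insurer** prices expected claims
  `E[C|q] = ∫ C(q, θ) f(θ) dθ` (Gauss–Legendre quadrature over the
  health-risk density), loads them for adverse selection
  (`P = P₀ + λ·E[C]`), and adjusts premiums dynamically,
  `dP/dt = γ(E[C] − P)`, with a closed-form-checked Euler scheme.
* **The government** tracks welfare
  `W = ΣU − ΣC + λ_health ΣH(q)` and moves subsidies and taxes by
  `dS/dt = β(W − W*)`, `dT/dt = δ(W − W*)`. Prices evolve as
  `dp/dt = κ(D − S) − η(p − p*)` under a hard per-step bound, and
  incentives `I(q) = β₁T(q) + β₂R(q) + β₃M(q)` are allocated greedily by
  marginal utility under budget, cost-effectiveness-threshold and
  smoothness constraints (checked against exhaustive search in the
  tests).

A reinforcement-learning layer optimizes the subsidy/tax policy on a
finite lattice: tabular softmax policy, REINFORCE gradient with a
mean-return baseline (validated against finite differences of the
exactly enumerated objective), and TD(0) welfare-value updates
(validated against the direct linear Bellman solve).

## Worked example

The built-in reference cohort compares ten patients, four managed
without AI support and six with an AI-driven recommendation system:

```r
library(healthmarket)
summarize_cohort(builtin_cohort())
```

```
                                     control              ai
patients                                   4               6
with observed cost                         4               6
mean cost                          44,750.00       34,333.33
mean misdiagnosis (%)                  18.50            7.55
misdiagnosis range (%)           16.20-20.50       6.50-9.00
mean premium (/mo)                  1,140.00          985.00
access rate                             0.25            1.00

cost reduction:         10,416.67 (23.28%)
premium reduction:      155.00 (13.60%)
misdiagnosis reduction: 10.95 pp (59.19%)
```

Mean treatment cost falls from ¥44,750 to ¥34,333 (23.3%), monthly
premiums fall 13.6% (inside the 10–15% band such comparisons typically
report), the worst AI-group misdiagnosis rate is 9.0% against a control
range of 16.2–20.5%, and every AI-group patient proceeded to treatment
versus one in four controls. Aggregates skip missing cells, and
relative reductions are reported only when the control mean is
positive.

Simulating the shipped stable baseline market:

```r
traj <- run_simulation(baseline_scenario())
summarize_trajectory(traj)
#> $final_price           4.857143   # the market-clearing price 34/7
#> $final_mean_premium   64.285714   # expected claims at equilibrium consumption
#> $final_welfare      3033.832556   # equals the welfare target W*
#> $converged                 TRUE
#> $steps_to_convergence       534   # of 1200 ticks (dt = 0.05)
```

At the terminal state the price, premium and policy drift residuals all
vanish simultaneously (≤ 1e-10). Scenario files are YAML or JSON
(`load_config()` / `save_config()`), and a thin command-line wrapper
ships at `system.file("cli", "healthmarket", package = "healthmarket")`
with subcommands `simulate`, `optimize-policy`, `summarize-cohort` and
`generate-cohort`, each writing a run manifest next to its outputs.

See the vignette (`vignettes/market-model.Rmd`) for the full model
description, parameter meanings, numerical choices and limitations.

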