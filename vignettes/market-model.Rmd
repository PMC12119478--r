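---
title: "A dynamic equilibrium model of healthcare markets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic equilibrium model of healthcare markets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthmarket)
```

`healthmarket` simulates a healthcare market as a coupled dynamical
system with four kinds of agents — consumers, providers, an insurer and
a government — plus a reinforcement-learning layer that optimizes the
government's subsidy/tax policy, and a cohort summarizer for
per-patient economic outcome tables. This vignette is the package's own
account of the model, its assumptions, the tunable parameters, the
numerical choices, and what the test suite does and does not establish.

## The model

### Consumers

Each consumer values care quantity $q$ and net income $y$ through the
quadratic utility

$$U(q, y) = a q - \tfrac{b}{2} q^2 + c\, y, \qquad b > 0,$$

the minimal concave family with a closed-form demand. Facing price $p$
that may be drifting at rate $\dot p$, the first-order condition
$U'(q) = \lambda (p + \dot p)$ gives the consumption rule

$$q^*(p, \dot p) = \max\!\left(0,\; \frac{a - \lambda (p + \dot p)}{b}\right),$$

where $\lambda$ is the consumer's budget multiplier. Two modelling
caveats are deliberate:

* $\lambda$ is a configuration parameter, not solved from the budget
  constraint — the model that this package implements never specifies
  its origin. `consumption_foc_residual()` verifies the static optimum;
  `euler_residual()` exposes the intertemporal (Euler) condition purely
  as a diagnostic, because the static rule is not guaranteed to satisfy
  it and the package does not pretend otherwise.
* The closed form can go negative at high prices; quantities are
  physical, so it is clipped at zero.

With insurance coverage $\alpha \in [0,1]$, moral hazard scales the
marginal-utility condition: the insured demand $q'$ solves
$U'(q') = \alpha\, U'(q^*)$, i.e.
$q' = (a - \alpha(a - b q^*))/b$, capped at the satiation point $a/b$
(for small $\alpha$ the uncapped condition has no solution once $U'$
turns negative). $\alpha = 1$ reproduces the uninsured optimum and
$\alpha = 0$ gives satiation; `moral_hazard_demand()` is monotone
between the two. Subsidies act through the effective price
$p' = p - T(q)$; a subsidy larger than the price makes $p'$ negative,
which is allowed (a floor would silently change welfare) but flagged.

### Providers and market clearing

Providers carry the convex quadratic cost
$C(q) = c_0 + c_1 q + c_2 q^2$ (the minimal convex family with a
closed-form marginal cost $MC = c_1 + 2 c_2 q$) and supply the
profit-maximizing quantity $q = \max(0, (p - c_1)/(2 c_2))$. Market
clearing $\sum_i q_i(p) = \sum_j q_j(p)$ is solved by plain bisection
(`market_clearing_price()`): bracket-safe for any monotone excess
demand, unlike Newton steps, at negligible cost. A reduced-form
exponential demand $D(p) = d_0 e^{-\epsilon p}$ is also available; its
price elasticity is $-\epsilon p$, which the central-difference
estimator `price_elasticity()` reproduces to $10^{-6}$ at step
$h = 10^{-5}$.

### Insurance

The insurer's expected claim cost integrates the claim function over
the health-risk density, $E[C|q] = \int C(q,\theta) f(\theta)\,
d\theta$, by 64-node Gauss–Legendre quadrature (smooth integrands,
spectral accuracy, deterministic; the density is checked to integrate
to 1 first). Premiums respond in three ways:

* adverse-selection loading $P = P_0 + \lambda_{risk} E[C|\theta]$,
* the dynamic adjustment $dP/dt = \gamma (E[C] - P)$, discretized by
  explicit Euler so the fixed point $P = E[C]$ is exact and the
  discrete path can be checked against the closed form
  $P(t) = E + (P_0 - E)e^{-\gamma t}$,
* the risk-adjusted form
  $P = P_0 + \lambda_{risk} E[C|\theta] - \rho_{incentive} I$, which
  can go negative for large incentives and is therefore clipped at zero
  with a flag.

Portfolio balance $\sum_i P_i I_i = \sum_i E_i I_i$ is one linear
equation in a uniform premium shift, solved in closed form by
`solve_base_premium()` (idempotent by construction). The exposure
weights $I_i$ appear only here: the model conditions expected claims on
an "intervention level" but its integrand does not contain it, so the
package treats exposure strictly as a balance weight and notes the gap.

### Dynamic pricing

Prices follow the dampened excess-demand dynamic

$$\frac{dp}{dt} = \kappa\,(D - S) - \eta\,(p - p^*),$$

with two regulatory guards: the per-step change is clipped to
$\pm \delta p_{max}$ and the price floored at zero. The bound is
interpreted *per step of size* $\Delta t$ — the only reading consistent
with the discretization at fixed $\Delta t$. With $D \equiv S$ the
discrete map contracts whenever $\eta\,\Delta t < 2$, and the path
matches the $e^{-\eta t}$ envelope to $O(\Delta t)$; with $\eta = 0$ a
flagged fixed point satisfies $D(\bar p) = S(\bar p)$ to the stated
tolerance (default $10^{-8}$ on the per-step update, far below economic
precision).

### Incentives

The incentive paid at consumption $q$ is
$I(q) = \beta_1 T(q) + \beta_2 R(q) + \beta_3 M(q)$ — tax rebate,
risk-adjusted benefit, adherence reward — each a named nonnegative
form. Allocation across consumers maximizes summed utility subject to

* a total budget $\sum_i I_i \le B_{max}$,
* a marginal cost-effectiveness threshold: grants require marginal
  utility per currency unit $\ge \lambda_{min}$,
* a smoothness bound $|I_i(t+1) - I_i(t)| \le \Delta_{max}$.

The model states this optimization but no algorithm. The package uses
greedy marginal-utility allocation on a grid: with concave utilities it
is optimal in the continuous limit, every grant is trivially auditable
against all three constraints, and the tests compare it against
exhaustive grid enumeration (agreement within one grid-step's utility).
Whether the optimization is over the $\beta$ weights or the
per-consumer amounts is ambiguous in the source model; the package
allocates per-consumer amounts and keeps the $\beta$s as configuration.
The smoothness constraint is two-sided, so each allocation is boxed to
$[\max(0, I^{prev} - \Delta_{max}),\; I^{prev} + \Delta_{max}]$; when
the lower bounds alone exceed the budget the instance is infeasible and
the allocator says so rather than quietly violating a constraint.
Marginal utility per incentive unit comes in two exposed modes: a pure
income effect ($\partial U/\partial I = c$, constant) or a configured
consumption response $q(I) = q_0 + kI$ giving the concave
$(a - b(q_0 + kI))k$.

### Government

Welfare is $W = \sum_i U_i - \sum_j C_j + \lambda_{health} \sum_i
H(q_i)$ with the concave benefit $H(q) = \max(0, h_1 q - h_2 q^2)$ (the
model says only that $H$ "represents health benefits"; a concave family
with exposed parameters is the minimal sensible choice). Subsidy and
tax evolve as $dS/dt = \beta (W - W^*)$, $dT/dt = \delta (W - W^*)$ —
*both* moving in the same direction, which is how the model writes it;
the package implements it literally and documents the economic oddity
rather than silently "fixing" it. The target $W^*$ is never defined by
the model; by default the package computes the welfare of the
no-intervention market-clearing equilibrium at setup, which keeps runs
self-contained, and `w_star` remains overridable. The discounted
objective $\int_0^T e^{-\rho t} W(t)\,dt$ is evaluated by the
trapezoidal rule ($O(\Delta t^2)$, verified by step-halving).

### Reinforcement learning

Policy optimization runs on a finite lattice of (subsidy, tax) states
with per-instrument moves $\{-1, 0, +1\}$ (9 actions), deterministic
clipped transitions by default, and any configured stochastic kernel
otherwise (rows validated to sum to 1). The policy is tabular softmax —
the model names $\pi(a|S,T)$ but no parametric family, and tabular
softmax makes the exact objective computable by enumeration, so the
gradient estimator can be tested against finite differences of the
exact value rather than against itself. The REINFORCE estimator uses
whole-episode returns with a mean-return baseline (variance reduction
that preserves the estimator's expectation; toggleable). The recursive
welfare update of the source model is self-referential as printed
($W_{t+1}$ on both sides); the package reads it as the standard TD(0)
update $W(s) \mathrel{+}= \alpha (r + \gamma W(s') - W(s))$, recorded
as an interpretation. The value-update and gradient-ascent components
are kept as independent utilities because the model never combines
them. Rewards for the lattice built by `mdp_from_config()` evaluate
social welfare at the static equilibrium induced by the policy-adjusted
first-order conditions (marginal utility $= p - T$, marginal cost
$= p - S$, taken literally from the model's optimality conditions).

### The coupled engine

`run_simulation()` advances one tick as: consumption → demand/supply →
price step → expected claims → premium steps → incentive allocation →
welfare → policy step. The source model never sequences its blocks;
this order is the package's choice (demand must precede pricing,
welfare must precede the policy step). Demand coupling is configurable
— `"structural"` (sum of consumer optima) or `"reduced"` (exponential
form) — because the model presents both without connecting them. The
engine is deterministic given the configuration: the dynamics contain
no noise, so bit-identical reproducibility is structural, and the
single RNG seed governs only the synthetic-data and episode-sampling
substreams (one independent substream per module, so adding a module
never perturbs another's draws).

One coupling is deliberately absent: the model never connects the
dynamic subsidy/tax levels back into demand (its static subsidy
function is a distinct object), so welfare does not respond to the
policy instruments inside the engine. Consequently the policy dynamic
reaches a fixed point only when welfare itself reaches $W^*$. The
shipped `baseline_scenario()` is constructed so that happens: no price
dampening ($\eta = 0$, so the price converges to the clearing price),
$W^*$ at its default (the clearing-equilibrium welfare), full coverage,
and no incentive program ($B_{max} = 0$, so terminal welfare carries no
incentive income that $W^*$ would not know about). At its terminal
state the price, premium and policy drift residuals all vanish
simultaneously; its terminal values (price $34/7$, mean premium
$450/7$, welfare $\approx 3033.83$) are pinned in the tests both
against the analytic equilibrium and as golden regression numbers.
Incentive-enabled scenarios run fine but no convergence is asserted for
them.

## Parameters at a glance

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `a`, `b`, `c` | utility coefficients | 10, 2, 1 | utils per unit, per unit², per currency |
| `lambda_consumer` | budget multiplier | 1 | utils per currency |
| `coverage` | insurance coverage $\alpha$ | 1 | share |
| `c0, c1, c2` | provider cost coefficients | 0, 1, 0.5 | currency |
| `d0`, `epsilon` | reduced-form demand | 100, 0.02 | quantity, per currency |
| `kappa` | price sensitivity | 0.2 | currency per quantity per time |
| `eta_stabilize` | price dampening | 0 | per time |
| `dp_max` | per-step price bound | 5 | currency |
| `p0`, `lambda_risk`, `rho_incentive` | premium pricing | 100, 0.5, 0 | currency, ratio, per currency |
| `gamma_premium` | premium speed | 0.5 | per time |
| `beta_s`, `delta_t` | policy speeds | 0.05 | per welfare-unit per time |
| `lambda_health` | welfare weight on $H$ | 1 | — |
| `b_max`, `delta_max`, `lambda_min`, `grid` | incentive constraints | 10, 5, 0, 0.25 | currency (first three), currency |
| `gamma_rl`, `eta_lr`, `td_step` | RL discount, learning rate, TD step | 0.9, 0.05, 0.1 | — |
| `step`, `horizon`, `discount_rate` | time discretization | 0.05, 20, 0.03 | time units |

The greek-letter symbols of the underlying model are heavily
overloaded ($\lambda$, $\rho$, $\gamma$, $\eta$, $T$, $S$, $I$,
$\alpha$ each carry two to four meanings); every field above names one
role and appears exactly once in the configuration schema.

## Synthetic cohorts

`generate_cohort()` emulates two-group patient outcome tables: per-group
cost, misdiagnosis-percentage and monthly-premium distributions plus an
access probability. The underlying model states no distributions for
any of these quantities, so the families are the package's own choice,
picked once: normal truncated at 0 for cost and premium, normal
truncated to $[0, 100]$ for misdiagnosis, Bernoulli for access — the
simplest families matching the scale of the built-in reference cohort,
with all parameters exposed. The defaults match that cohort's group
moments (control: cost $44{,}750 \pm 4{,}800$, misdiagnosis
$18.5 \pm 1.9$, premium $1{,}140 \pm 50$, access 0.25; AI group: cost
$34{,}333 \pm 2{,}500$, misdiagnosis $7.55 \pm 1.0$, premium
$985 \pm 48$, access 1). Missing cells are explicit `NA`, never zero,
and every aggregate skips them.

What the generator does *not* emulate: correlation between cost,
misdiagnosis and premium within a patient; non-normal tails (real cost
distributions are right-skewed); longitudinal structure; informative
missingness (in real tables, *why* a cell is missing usually carries
information). Passing moment-recovery tests therefore show that the
pipeline is statistically faithful to its own generative model, not
that it is calibrated to any real healthcare market.

## Numerical choices

* Explicit Euler for every ODE (premium, price, policy), user-set
  `step` (engine default 0.05; accuracy checks run at $10^{-3}$): keeps
  fixed points exact and paths testable against closed forms.
* Bisection for clearing prices (bracket-safe under unspecified
  functional forms), tolerance $10^{-8}$ on excess demand.
* Gauss–Legendre, 64 nodes, for expected claims; density normalization
  checked to the quadrature tolerance ($10^{-6}$ default).
* Greedy allocation ties broken by lowest consumer index
  (deterministic); grants in grid steps of 0.25 currency by default.
* Convergence flags use absolute per-step updates below `tol`
  ($10^{-6}$ for the engine, $10^{-8}$ for standalone price paths); at
  a flagged fixed point the drift residual is below `tol / step`.
* Degenerate inputs: zero demand makes elasticities undefined (error);
  identical demand and supply over a bracket returns the midpoint;
  empty portfolios, empty cohorts and empty episode lists are errors,
  not silent zeros.
* Clipping is always flagged (attributes `clipped`, `floored`,
  `negative`) so audits can distinguish a binding constraint from a
  quiet one.

## Problem sizes in the test suite

The suite checks statistical properties at sizes chosen to make the
checks sharp but cheap: cohort moment recovery at $n = 10{,}000$ per
group (3 standard errors), Monte-Carlo return agreement at $10{,}000$
episodes, the REINFORCE-vs-finite-difference comparison at $8{,}000$
episodes in the unit test and $30{,}000$ in the end-to-end test (the
3-SE criterion is scale-free in the episode count), 200 gradient-ascent
iterations of 100 episodes on a two-state toy process, $10{,}000$ TD
sweeps on a two-state chain against the direct linear Bellman solve,
and exhaustive-search comparisons on allocation instances with up to 3
consumers and 13 grid levels each.

## Known limitations

* No strategic behavior: providers do not set prices, consumers do not
  anticipate policy.
* The consumer's Lagrange multiplier is exogenous; the Euler equation
  is diagnostic only.
* Policy instruments do not feed back into demand inside the engine
  (see above), so policy convergence is meaningful only relative to a
  consistent $W^*$.
* No claims at the individual-event level, no actuarial credibility,
  no calibration to real market data, and no statistical inference on
  cohort summaries (the reference table ships without uncertainty).
* The built-in reference cohort's control group contains a
  misdiagnosis value of 20.5%, outside its nominal 16–20% range, and
  its AI-group mean cost computes to 34,333.33 where the accompanying
  narrative rounds to "around 34,400"; the package reports the computed
  values and flags the discrepancies instead of inventing a rounding
  rule.
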