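---
title: "Eco-evolutionary games: models, methods, and numerical choices"
author: "ecogames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary games: models, methods, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogames)
```

## The model

Many strategic interactions play out in an environment that the strategies
themselves reshape: harvesting effort depletes the fish stock that makes
harvesting profitable, nitrogen-fixing legumes enrich the soil that
advantages their grass competitors, polluting technologies degrade the
commons that set their own payoffs. `ecogames` implements the linear
two-strategy version of this feedback loop as a planar dynamical system.

Let $x$ be the frequency of the *low-impact* strategy L (the other strategy
is H), and let $n \in [0,1]$ be a normalized environmental state, with
$n = 1$ the rich (or clean) state. Payoffs interpolate linearly between a
poor-state and a rich-state game matrix,
$$\Pi(n) = (1-n)\begin{pmatrix}R_0&S_0\\T_0&P_0\end{pmatrix}
         + n\begin{pmatrix}R_1&S_1\\T_1&P_1\end{pmatrix},$$
and two-strategy replicator dynamics reduce to
$$\dot x = x(1-x)\, g(x,n), \qquad g = \pi_L - \pi_H,$$
with the strategy-update speed normalized to one (the mean fitness of the
full replicator equation cancels exactly in this reduction and is therefore
never computed). Because replicator dynamics only see payoff *differences*,
the entire strategy dynamic is captured by four numbers, the incentives to
lead or follow strategy change at the corners of the state space:
$\Delta_L^1 = T_1-R_1$ (lead a "gold rush"), $\Delta_H^1 = P_1-S_1$ (follow
it), $\delta_L^0 = R_0-T_0$ (follow an "environmental movement"), and
$\delta_H^0 = S_0-P_0$ (lead it). The gain function is the bilinear surface
with those four corner values; `canonical_payoffs()` provides one
representative $\Pi(n)$ for a given incentive set (the choice is not unique;
we zero the H rows, which makes the reduction exactly invertible).

Three environment classes close the loop:

* **renewing resource** — a logistic stock harvested at strategy-dependent
  effort; after an affine normalization the state obeys
  $\dot n = \epsilon\,(r - q(e_L n + e_H(1-n)))(x-n)$;
* **decaying resource** — a pollutant with first-order decay,
  $\dot n = \epsilon\alpha(x-n)$;
* **tipping points** — a continuum of environmental units that flip when
  $x$ crosses their threshold, $\dot n = \epsilon n(1-n)(x - F^{-1}(n))$
  for a threshold CDF $F$; the zero-variance (Heaviside) limit recovers the
  classic model without intrinsic environmental dynamics.

$\epsilon$ is the single timescale ratio of environmental to strategic
change (the intrinsic-dynamics and strategy-impact timescales are taken
equal, so one ratio remains). For the renewing class the effort bounds
$0 \le e_L < e_H < r/q$ keep the growth bracket positive, so both
intrinsic-dynamics classes share the attracting nullcline $n = x$; this is
why they produce the same qualitative outcomes and why the package analyzes
them with common machinery.

## Equilibria, stability, and the critical feedback speed

On $n = x$ the gain restricts to a quadratic, so the system has at most
four fixed points: $(0,0)$, $(1,1)$, and up to two interior roots. The
classification logic is exact:

* $(0,0)$ is stable iff $\delta_H^0 < 0$ and $(1,1)$ iff $\Delta_L^1 < 0$
  (the conditions are treated as biconditional for generic nonzero
  incentives, returning `nonhyperbolic` within $10^{-9}$ of the boundary;
  the unstable edge is formally a saddle because the environmental
  direction still attracts);
* the interior root where the Jacobian determinant is negative is the
  saddle $x_+^*$; the other, $x_-^*$, can be stable or can lose stability
  in a Hopf bifurcation. The determinant sign at an interior root equals
  $-\mathrm{sign}\,\frac{d}{dx}g(x,x)$ for both families, so the kind is
  assigned from the incentives alone.

Instability of $x_-^*$ requires $\Delta_H^1 + \delta_L^0 > 0$,
$\Delta_H^1\delta_L^0 > \Delta_L^1\delta_H^0$, and
$\epsilon < \epsilon_{\mathrm{crit}}$. `epsilon_crit()` computes the
threshold primarily by bisecting the sign change of the leading eigenvalue
real part of the exact Jacobian at $x_-^*$ over
$\epsilon \in (10^{-8}, 10^4)$ — the bisection definition is primary, so no
transcribed closed form has to be trusted. As an independent cross-check we
derived the trace-zero condition: at $x_-^*$ the Jacobian trace is
$x(1-x)g_x - \epsilon D$ with $D = \alpha$ (decaying) or
$D = r - q(e_L x^* + e_H(1-x^*))$ (renewing), giving
$\epsilon_{\mathrm{crit}} = x^*(1-x^*)\,g_x(x^*,x^*)/D$, valid when the
determinant there is positive ($g_x + g_n < 0$). The two routes agree to
$10^{-6}$ relative in the test suite, and for the worked panel-b incentive
set $(2, 1, 3, 1)$ both give $\epsilon_{\mathrm{crit}} \approx 0.0654$ with
$x_-^* = 1/\sqrt 3$.

`classify_regime()` maps a system to its qualitative outcome. The signs of
$(\Delta_L^1, \delta_H^0)$ pick one of four panels; within the mixed-sign
panels an unstable $x_-^*$ can mean either a bistable edge-plus-cycle
configuration or pure edge dominance (the cycle disappears in a global,
homoclinic-type collision with the saddle as $\epsilon$ falls). The
boundary between those sub-regimes has no closed form in the main-text
analysis, so it is resolved by a *deterministic simulation probe*: five
fixed interior starts integrated to $t = 500/\epsilon$ and passed to the
attractor diagnostics. For the worked mixed-incentive set
$(-1/8, 4, 1, 2)$ this yields the ladder stable interior
($\epsilon = 0.4$) → bistable edge + cycle ($0.25$) → low-impact dominance
($0.05$), with $\epsilon_{\mathrm{crit}} \approx 0.262$ and the cycle
window ending near $\epsilon \approx 0.24$.

## Numerical integration

No ODE solver package is assumed: the integrator is an adaptive
Dormand–Prince 5(4) pair written for this planar system (compiled for the
four closed-form environment classes, with a pure-R reference
implementation that also serves custom tipping CDFs and cross-checks the
compiled path to $10^{-7}$).

Numerical contracts, all test-enforced:

* **containment** — accepted states may overshoot $[0,1]^2$ by at most
  $10^{-8}$ before being clipped; larger excursions raise an error carrying
  the partial trajectory, so solver faults are never silently masked;
* **edge invariance** — $x \in \{0,1\}$ is preserved exactly (the
  replicator factor vanishes identically at the RK stages), and tipping
  environments preserve $n \in \{0,1\}$ exactly;
* **convergence exit** — integration stops early only when the
  vector-field norm stays below $10^{-10}$ for a sustained window (5 time
  units), a criterion chosen over state-difference tests so that slow
  passages near saddles are not misreported as convergence;
* **tolerances** — defaults `rtol = atol = 1e-9`; cycle amplitudes near the
  Hopf point are tolerance-sensitive, and the suite checks that halving the
  tolerances moves amplitude and period by less than 1%.

Dense output for diagnostics uses cubic Hermite interpolation over accepted
steps.

## Attractor diagnostics and basins

`diagnose_attractor()` discards a transient fraction (default 0.5) and then
distinguishes fixed points (terminal field norm $< 10^{-8}$), absorbed edge
states (within $10^{-6}$ of a corner), and limit cycles. Cycles are
detected from the sequence of local maxima of $x(t)$ — refined by quadratic
interpolation — rather than by Poincaré sections, which stays robust when
cycles hug the edges of the square; a cycle requires peak-to-trough
amplitude above `amplitude_floor = 1e-3` (separating genuine cycles from
slowly damped foci near the Hopf point) with less than 1% amplitude drift
across the last three periods. Anything else is `undetermined`, with
automatic doubling of the time span (at most three times); a too-short
trajectory is never silently reported as a fixed point. Slowly *growing*
transient spirals very close to $\epsilon_{\mathrm{crit}}$ can still defeat
any finite-time criterion; regime probes therefore avoid the immediate
neighborhood of the threshold.

`estimate_basins()` integrates from every interior point of a regular grid
and pools diagnoses into basin labels (fixed points matched to $10^{-3}$).
Basin maps for the mixed-incentive system are stable to doubling the
integration time within the 2% of cells that sit near basin boundaries.

## Case studies

* **Common-pool harvesting.** Profit $pq\eta e_i - we_i$ is linear in the
  stock, so the model is a special case of the renewing-resource game with
  $\Delta_L^1 = \Delta_H^1$ and $\delta_L^0 = \delta_H^0$: leader and
  follower incentives coincide, the system sits *exactly* on the cycle
  boundary $\Delta_H^1\delta_L^0 = \Delta_L^1\delta_H^0$ (asserted to
  $10^{-12}$ relative, by two independent construction routes), and no
  positive $\epsilon$ produces cycles — the only outcome is a stable mix at
  $x_-^* = \delta_L^0/(\delta_L^0 + \Delta_L^1)$. A 10% perturbation of
  $\Delta_H^1$ re-opens a finite Hopf threshold, which is why near-boundary
  systems are fragile.
* **Grass–legume competition** ships as a predicate over user-supplied
  incentives, not a mechanistic nitrogen model: the ecological argument is
  purely about signs and orderings (all incentives positive, leading harder
  than following), which jointly imply the cycle-permitting inequality.
* **Tipping environments.** The Weitz limit is implemented as the limiting
  drift $\tilde\epsilon\, n(1-n)(\theta x - (1-x))$ with
  $\mu = 1/(1+\theta)$, $\epsilon = (1+\theta)\tilde\epsilon$, rather than
  by inverting a degenerate CDF (avoids division by zero and is exact per
  the limiting statement). Uniform-width trajectories converge monotonically
  to the Heaviside model's as the width shrinks; for any positive width the
  intrinsic dynamics reappear and oscillations once again require
  sufficient timescale separation. Custom threshold CDFs whose support
  exceeds $[0,1]$ are accepted as-is, a deliberate permissiveness: the
  $n(1-n)$ factor keeps the drift well-defined regardless.

## Design decisions and limitations

* Dynamics consume `incentive_params`, not payoff matrices: the replicator
  equation depends only on $\pi_L - \pi_H$, and this is how practitioners
  parameterize these models. Payoff-level code paths are exercised through
  `canonical_payoffs()`.
* Raw-stock simulation (`stock_drift()`) is retained solely as a
  verification oracle for the affine normalization — production dynamics
  always run on $n$. The endpoint-matching transform (pure-H steady state
  to $n=0$, pure-L to $n=1$) is verified against the normalized drift by
  integration rather than assumed, since its derivation is not in the
  main-text analysis.
* Analytic equilibrium enumeration is restricted to the renewing/decaying
  families; tipping environments are probed by simulation only (their
  heteroclinic structure in the exact Weitz limit is prior work we do not
  re-derive).
* Strict inequalities carry a $10^{-9}$ degeneracy tolerance; anything
  closer is reported `boundary_degenerate` or `nonhyperbolic` rather than
  forced into a generic class.
* Simulation-based classification (the c/d sub-regime probe, basin maps) is
  faithful but finite: a cycle with a basin missed by all five probe starts,
  or dynamics slower than the probe horizon, would be misclassified. The
  probe is deterministic, so such a misclassification would at least be
  reproducible.
* Nonlinear payoff structures (market pricing, frequency-dependent harvest
  efficiency), more than two strategies, spatial structure, and
  truncated-normal tipping distributions are out of scope; the custom-CDF
  hook is the supported extension point.

## A worked example

```{r example, eval = FALSE}
inc <- incentive_params(deltaL1 = 2, deltaH1 = 1, dL0 = 3, dH0 = 1)
env <- decaying_resource(alpha = 1, epsilon = 0.02)
sys <- ecogame(inc, env)
summary(sys)            # 3 fixed points, regime: limit_cycle
tr <- simulate(sys, x0 = 0.9, n0 = 0.6, t_end = 2000)
diagnose_attractor(tr)  # limit cycle, amplitude ~ 1, period ~ 110
plot(sys, trajectories = tr)
```
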