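---
title: "Methods: the care-cooperation replicator model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the care-cooperation replicator model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caresynergy)
```

## The model

Two bounded-rational populations interact repeatedly: elderly social care
organizations, a fraction $x$ of which play *participation* (offering
health care services on top of social care), and health care
organizations, a fraction $y$ of which play *participation* (offering
elderly social care on top of health care). Eleven nonnegative scalars
describe the stakes (see `?game_parameters`): benefits $U_1, U_2$ and
$R_1, R_2$, costs $P_1, P_2$ and $C_1, C_2$, and government subsidies
$S_1, S_2, S_1'$. The subscript 1 variants apply under bilateral
cooperation, the subscript 2 variants when an organization goes it alone.
The model assumes the go-it-alone variants are strictly larger
($U_2 > U_1$, $P_2 > P_1$, $R_2 > R_1$, $C_2 > C_1$, $S_2 > S_1$):
providing the other sector's services yourself earns and costs more than
buying them from a partner. `validate_parameters()` enforces these
orderings strictly by default, but they can be relaxed
(`strict = FALSE`) for exploratory use, because they are modelling
assumptions rather than mathematical requirements — every published sweep
respects them.

Under the bimatrix payoffs of `payoff_matrix()`, replicator dynamics give

$$\dot x = x(1-x)\,(a y + b), \qquad \dot y = y(1-y)\,(c x + d),$$

with the four *reduced coefficients*

$$a = U_1 - U_2 + P_2 - P_1 + S_1 - S_2,\quad b = U_2 + S_2 - P_2,$$
$$c = R_1 - R_2 + P_1 - S_1' + C_2 - C_1,\quad d = R_2 + S_1' - C_2.$$

Everything the eleven raw parameters do to the dynamics they do through
$(a, b, c, d)$; `reduced_coefficients()` exposes them, and the test suite
uses the identity as an oracle (parameter sets with equal coefficients
must behave identically, which cross-checks independent sweeps against
one another).

## Equilibria and stability

The five candidate equilibria are the corners $O(0,0)$, $A(0,1)$,
$B(1,0)$, $C(1,1)$ and, when it falls strictly inside the square, the
interior point $x^* = (C_2-R_2-S_1')/c$, $y^* = (P_2-U_2-S_2)/a$. Local
stability is read off the Jacobian: $\det J > 0$ and
$\operatorname{tr} J < 0$ is an evolutionary stable strategy (ESS), both
positive is a source, $\det J < 0$ a saddle. The interior point always
has $\operatorname{tr} J = 0$; when $\det J < 0$ there we follow the
convention of labelling it a saddle even though linearization is
inconclusive for a non-hyperbolic point in general — in this system the
label is correct, since the off-diagonal Jacobian structure at the
interior point gives real eigenvalues $\pm\sqrt{-\det J}$.

All sign comparisons use an absolute tolerance `eps = 1e-12`
(configurable in every classifier); a determinant or trace within `eps`
of zero yields `"indeterminate"` rather than a guess, because the
analysis assumes strict inequalities.

An ESS at $A$ means the *health-care-led* integrated care model, at $B$
the *social-care-led* model, at $C$ *bilateral cooperation*; an ESS at
$O$ means no integrated service. When $C$ is an ESS
($U_1+S_1>P_1$ and $R_1+P_1>C_1$), the sign pair
$(U_2+S_2-P_2,\; R_2+S_1'-C_2)$ selects one of four stability scenarios:
$(-,-)$ is scenario 1 (bistable: $O$ and $C$ both ESS, interior saddle),
$(-,+)$ scenario 2, $(+,-)$ scenario 3, $(+,+)$ scenario 4 (in 2–4 the
interior point leaves the square and $C$ is the unique ESS). The
numbering is reverse-engineered from the four published scenario
definitions and is pinned down by the regime tests, which require the
full five-point stability pattern of each scenario's column.

## Basin area and sensitivities

In scenario 1 the interior saddle's stable manifold separates the square
into the basin of $O$ and the basin of $C$. The basin of bilateral
cooperation (region $ACBE$) has area

$$S_{ACBE} = \tfrac12(1 - x^*) + \tfrac12(1 - y^*) = 1 - (x^* + y^*)/2,$$

the two-triangle construction over the saddle. We use the simplified
form internally — it is algebraically identical and has simpler
partials — and keep the two-triangle form in a test. `basin_area()`
refuses to run outside scenario 1, naming the violated condition; the
area construction is meaningless elsewhere.

`area_sensitivity()` differentiates $S_{ACBE}$ in each parameter, either
from the hand-derived closed form (each parameter enters only through
the quotients $x^*$, $y^*$) or by central finite differences with
relative step $h = 10^{-6}\max(1, |\theta|)$, chosen for second-order
accuracy; the two routes must agree to about $10^{-5}$ relative and both
are exercised in the tests. Inside the scenario-1 region all benefit and
subsidy derivatives are positive and the $P_2, C_1, C_2$ derivatives
negative. $P_1$ is the exception: it enters $x^*$ and $y^*$ with
opposite effect, so its sign depends on where it is evaluated (it is
positive near the low end of its feasible range and negative near the
high end). Its row is therefore *always* annotated globally
indeterminate, even when the local derivative has a clear sign — the
claim being annotated is global, not local. The published sign table
never states where it was evaluated; we verify it at the printed
baseline and, more stringently, as a monotonicity property at ±h around
hundreds of random scenario-1 parameter sets.

## Numerical integration

The integrator is an adaptive Dormand–Prince 5(4) pair written in C++
(deSolve is deliberately not a dependency; the system is two smooth ODEs
and the compiled core keeps the brute-force cross-checks cheap), with
fixed-step RK4 and explicit Euler as independent oracles. Defaults:
`rtol = 1e-8`, `atol = 1e-10`, horizon `t_max = 500` replicator time
units. The source publication never states its integration scheme or
step size, so accuracy is instead set high enough that every reported
outcome is integrator-independent — the tests require Euler at
`dt = 1e-4` to reproduce the adaptive method's outcome on a 9×9 grid of
initial conditions, and all flip thresholds to survive both a tolerance
halving and a switch to Euler.

Numerical choices worth recording:

* **Convergence test.** A trajectory has converged to a corner when it is
  within `delta = 1e-4` of it *and* the field magnitude is below
  `delta^2`. The second clause prevents crediting a corner during a slow
  transit near a saddle whose unstable manifold would later carry the
  state elsewhere.
* **Clamping.** The exact dynamics are forward-invariant on the unit
  square; numerically, states are clamped to $[0,1]^2$ after each step
  (default on). With clamping off and tight tolerances, excursions stay
  below $10^{-8}$ — asserted over 200 random runs.
* **Step cap.** Adaptive steps are capped at 1 time unit so that
  detected convergence times are localized to within a step; the
  monotone convergence-time orderings lean on this.
* **Separatrix rule.** A trajectory passing within $10^{-9}$ of the
  interior saddle is reported `"nonconvergent"` rather than assigned to
  either basin: on that measure-zero set the outcome is numerical noise,
  and honesty beats tidiness. A start placed exactly on the saddle
  therefore reports `"interior"` on moderate horizons and
  `"nonconvergent"` on long ones, once amplified round-off ejects it
  along the unstable manifold.
* **Time units.** Convergence is reported in continuous replicator time.
  The published figures use a discrete "evolution step" axis whose step
  size is never stated, so step counts are not reproducible quantities;
  only orderings of convergence times are asserted (e.g. raising $y_0$,
  $U_1$ or $R_1$ speeds convergence to bilateral cooperation).

## The sweep experiments

`run_figure_experiment()` hard-codes the ten published sweep setups: the
baseline parameter set $U_1{=}1$, $U_2{=}1.2$, $R_1{=}2.2$, $R_2{=}2.42$,
$S_1{=}1.4$, $S_1'{=}1.59$, $S_2{=}1.6$, $C_1{=}4$, $C_2{=}4.21$,
$P_1{=}2.23$, $P_2{=}3$ (scenario 1), with one quantity swept per figure
— initial conditions (`2a`–`3b`), benefits `U1`/`R1` (`4a`/`4b`), costs
`P1`/`C1` (`5ab`/`5c`), subsidies `S1`/`S1p` (`6a`/`6b`) — from
$x_0 = y_0 = 0.5$ unless the figure says otherwise. The scenario-1 sign
conditions are asserted at every grid point before integrating.
`flip_threshold` is the smallest grid value whose outcome differs from
the first grid point's; outcome sequences along a grid are not assumed
monotone (near the separatrix they need not be), so all change points
are reported and a non-converged grid point is flagged, never dropped.

The `P1` sweep is special: its long-run effect is genuinely undecided by
the theory, so no final-outcome value is asserted for it. What *is*
checked is the early-time claim — at $t = 0$ from $(0.5, 0.5)$, raising
$P_1$ lowers $\dot x$ (the social side's bracket loses $y\,\partial
a/\partial P_1 = -y$) and raises $\dot y$ (the health side's bracket
gains $x$), i.e. the cost transfer discourages the payer and encourages
the payee early on.

## What the tests do and do not establish

There is no synthetic-data generator in the usual sense: the model is
self-contained and every published input is printed, so the stated world
*is* the baseline parameter set and grids above. The random parameter
generators used by the property tests draw strictly-valid and
scenario-constrained sets by construction (margins of at least 0.05 on
every strict inequality) — they emulate the model's assumption space,
not any empirical distribution of Chinese care-sector economics, and no
such calibration is claimed. A green suite establishes that the
implementation reproduces the published analysis exactly and is
internally consistent under its own invariants; it says nothing about
the empirical adequacy of the game itself.

## Known limitations

* Exactly two populations with two strategies each; no finite-population
  or stochastic dynamics, no repeated-game memory, no discounting.
* Pointwise classification only: no continuation or global bifurcation
  analysis, and no center-manifold treatment of the non-hyperbolic
  interior point beyond the saddle label justified above.
* Basin-area sensitivities are defined (and computed) only inside
  scenario 1.
* Parameters are unbounded above by design; the model's source never
  bounds them.
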