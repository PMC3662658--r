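---
title: "Detecting the restorative/regenerative excitability switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the restorative/regenerative excitability switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcswitch)
```

## The model class and its timescale structure

`tcswitch` operates on conductance-based membrane models,

$$C\,\dot V = I_{app} - \sum_{ion} \bar g_{ion}\,\Big(\prod_j x_j^{p_j}\Big)(V - E_{ion}),
\qquad \dot x = \frac{x_\infty(V) - x}{\tau_x(V)},$$

with every gating variable declared as **fast** (millisecond range, spike
upstroke), **slow** (5–10× slower, spike initiation and downstroke), or
**ultraslow** (adaptation). The timescale class is an input, never inferred
from the kinetics: the same mathematical gate plays entirely different
dynamical roles depending on its class, and channel databases publish the
grouping. Ultraslow variables are frozen at fixed values and enter the
algebra as constants; they contribute no Jacobian row. Units are fixed
throughout at mV, ms, µA/cm², mS/cm², µF/cm²; the capacitance defaults to 1
and cancels from every sign decision, because all classification quantities
are expressed in conductance (current-slope) units.

Two kinetics dialects cover the models in scope: Boltzmann sigmoids
$x_\infty(V) = 1/(1+e^{-(V-V_{1/2})/k})$ with analytic slope
$x_\infty(1-x_\infty)/k$, and classic $\alpha/\beta$ rate expressions with
$x_\infty = \alpha/(\alpha+\beta)$, differentiated by Richardson-extrapolated
central differences (base step $10^{-3}$ mV, relative accuracy better than
$10^{-8}$ on these smooth rates — well inside every tolerance used
downstream). The removable $0/0$ singularities of the standard rate laws are
evaluated through `vtrap()`, which switches to a second-order series within
$|x| < 10^{-6}$ of the singular voltage. Gate monotonicity (activation
increasing, inactivation decreasing), $x_\infty \in (0,1)$ and $\tau > 0$
are verified numerically at construction on a 201-point grid over
$[-120, 60]$ mV rather than assumed; strict monotonicity is enforced away
from the voltage ranges where a steep sigmoid saturates to 0 or 1 in double
precision.

## Feedback weights and the balance equation

Write $F(V, x) = I_{app} - \sum I_{ion}$ for the net current. At an
operating point with all gates at steady state, each slow gate carries a
feedback weight

$$w_s(V) = \frac{\partial F}{\partial x_s}\,\frac{dx_{s,\infty}}{dV}
\quad [\mathrm{mS/cm^2}],$$

whose sign says whether the gate damps voltage perturbations (restorative,
$w_s < 0$: delayed-rectifier activation, transient-sodium inactivation) or
amplifies them (regenerative, $w_s > 0$: calcium-channel activation,
A-type potassium inactivation). The **slow balance**
$B(V) = \sum_s w_s(V)$ labels the model at its resting point;
`excitability_at_rest()` uses the most hyperpolarized stable equilibrium
and flags the model *mixed* when another stable equilibrium carries the
opposite sign (the coexistence of a regenerative down-state with a
restorative up-state). A model with no slow gates at all is labelled
*neutral* — there is nothing to balance — and a tolerance
$tol_B = 10^{-8}$ mS/cm², below the fixed-point solver's residual scale,
separates "balanced" from a genuine sign.

The central algebraic fact the package exploits is an exact arrowhead
identity. The Jacobian of a conductance model is an arrowhead matrix (each
gate couples only to voltage), and with all time constants set to one,

$$\det J_{unit} = \frac{(-1)^m}{C}\Big(\underbrace{\frac{\partial F}{\partial V}
+ \sum_{fast} w_f}_{s_{fast}(V)} + \underbrace{\sum_{slow} w_s}_{B(V)}\Big),$$

where $m$ is the number of live gates. The parenthesis is the *reduced
slope* over all fast and slow gates (`reduced_slope()`), computed with the
fast-gate partial sums accumulated before the slow ones so that the
decomposition `reduced_slope(fast∪slow) = reduced_slope(fast) + slow_balance`
holds *bit-exactly* in floating point, not merely to rounding — the test
suite asserts identity, not tolerance. Because no time constant appears on
the right-hand side, every sign decision and every critical point below is
invariant to arbitrary rescaling of the $\tau$'s; the suite re-solves with
randomized time constants and requires agreement to $10^{-10}$.

## The transcritical point and the affine current law

The switch between excitability types is located by solving two residuals
simultaneously in the voltage $V$ and one bifurcation parameter $\lambda$
(a maximal conductance, a reversal potential, or a frozen adaptation
value):

* balance: $B(V^*, \lambda^*) = 0$;
* fast-subsystem singularity: $s_{fast}(V^*, \lambda^*) = 0$.

By the identity above the two conditions force $\det J_{unit} = 0$, and the
crossing they pin down is transcritical: two equilibrium branches cross and
exchange stability. `solve_tc()` scans a $(V, \lambda)$ grid (defaults
161×81), traces the balance-root curves $\lambda_B(V)$ by sign-change
bracketing with linear interpolation, seeds a damped Newton iteration
(step-halving, ≤50 iterations, convergence at residual $< 10^{-9}$
mS/cm² and step $< 10^{-10}$) at every sign change of $s_{fast}$ along a
curve, deduplicates roots to $10^{-6}$ in both coordinates and orders them
by $V^*$. When the balance cannot vanish anywhere in the box — a model with
no regenerative mass, say — the solver raises a condition
(`tcs_no_balance_root`) naming the sign obstruction rather than returning
an empty table.

The applied current at the critical point, $I_{TC}$, is the unique value
making $V^*$ an equilibrium. Away from $\lambda^*$ the **affine current
law** $I_{app}(\lambda) = \sum I_{ion}(V^*, x_\infty(V^*); \lambda)$ keeps
the net steady current at $V^*$ constant — $V^*$ remains an equilibrium for
every $\lambda$, which is one of the defining conditions of the
transcritical crossing and guarantees that the observed switch reflects a
change in the membrane's dynamical properties, not its net current. The law
is affine in $\lambda$ for all three parameter kinds.

`verify_tc()` certifies a candidate numerically instead of relying on the
theory: (a) the reduced slope over all gates vanishes at the candidate
(absolute tolerance $10^{-6}$ mS/cm²; a $10^{-2}$ perturbation of
$\lambda^*$ fails this by two orders of magnitude); (b) fixed-point
branches exist on *both* sides of $\lambda^*$ inside a ±0.5 mV window
around $V^*$ — a fold has solutions on one side only. Because the crossing
branch can be steep in the parameter, the probe shrinks the parameter
offset geometrically (0.5, 0.1, 0.02, 0.004) until both branches fall
inside the voltage window; a fixed offset of 0.5 in both coordinates
misses the crossing branch already for the built-in squid-axon model.
(c) The stability of the branch through $V^*$ must flip across the
crossing.

## Continuation and event classification

`continue_fixed_points()` runs pseudo-arclength continuation with a secant
predictor and a 2×2 Newton corrector on the gate-eliminated reduced system
$(V, p)$ — valid because equilibria satisfy $x = x_\infty(V)$ exactly, and
fold-robust because the reduced system is two-dimensional. Step control:
initial $10^{-2}$, bounds $[10^{-6}, 0.5]$ in natural units, growth on ≤3
corrector iterations, halving on ≥8 or failure. Each accepted record is
annotated with the full Jacobian eigenvalues at *physiological* time
constants (Hopf positions are $\tau$-dependent; the determinant test and
balance are not), the unit-$\tau$ determinant test function, and the slow
balance. Events are refined to $10^{-8}$ in the parameter by
corrector-constrained bisection along the bracketing segment:

* **SN** — determinant sign change with a genuine fold;
* **TC** — determinant sign change where the slow balance also vanishes
  (within $10^{-4}$ mS/cm²) *and* a branch-crossing probe finds two
  equilibria on both sides; the probe runs under the sweep's own current
  law, which is what distinguishes a genuine crossing from a coincidentally
  balanced fold — the latter is labelled **degenerate**, never silently
  classified either way;
* **HB** — the real part of a complex eigenvalue pair crosses zero.

A det-zero on a model with no slow gates is classified SN directly.
`bifurcation_diagram()` seeds continuation from all equilibria at a few
parameter values, skips seeds lying on already-traced branches, and merges
event tables; a crossing seen from both branches through it is
de-duplicated with the TC label taking precedence, since the copy refined
along the transversal branch can land a hair off the exact crossing.

## Simulation and signature definitions

`integrate_model()` uses lsoda (relative tolerance $10^{-8}$, absolute
$10^{-10}$), restarted at each protocol discontinuity, sampled at 10
points/ms, with gate values clipped to $[0,1]$ inside the RHS as a guard
against tolerance-level overshoot. The electrophysiological markers have no
universal quantitative definitions, so the package fixes operational ones
and exposes them as arguments: spikes are upward crossings of 0 mV with a
2 ms refractory period and linearly interpolated times; latency is measured
from depolarizing-step onset to the first spike; an afterdepolarization is
a post-release hump exceeding 2 mV above rest without reaching spike
threshold within 200 ms; a plateau requires the voltage to stay 20 mV above
rest for more than 50 ms with at least two spikes after stimulus offset.
`bistability_test()` requires a transient depolarizing pulse (5 ms,
amplitudes scanned over roughly a decade) to leave the model spiking
periodically at least 500 ms after pulse offset at the holding current, and
a subsequent hyperpolarizing pulse to return it to rest — both attractors at
the *same* holding current. Signature metrics are stable to integrator
tolerance halving within the suite's asserted bounds.

## The built-in models

**Squid axon.** `build_hh()` is the modern-voltage parameterization
($\bar g_{Na} = 120$, $\bar g_K = 36$, $g_L = 0.3$ mS/cm²; $E_{Na} = 50$,
$E_K = -77$, $E_L = -54.4$ mV; $C = 1$; standard rate laws), with $m$ fast
and $h$, $n$ slow. Both slow weights are negative at rest — the model is
restorative in physiological conditions — but the potassium weight
$w_n = -4\bar g_K n^3 n_\infty'(V)(V - E_K)$ changes sign when $E_K$ rises
above the operating voltage, so $E_K$ is the canonical bifurcation
parameter. With the package's convention the switch sits at
$V^* \approx -61.8$ mV, $E_K^* \approx -59.9$ mV, $I_{TC} \approx -6.4$
µA/cm²; these coordinates are convention-dependent (the historical
parameterization shifts them), so they are validated against the in-repo
dense-grid oracle rather than against any external table. The diagram
against $E_K$ with the affine law installed shows SN → TC → HB in that
order, and the regenerative side passes the pulse bistability test while
the restorative side fails it.

**Planar caricature.** The two-variable fixture
$$\dot v = v - v^3/3 - w^2 + I, \qquad
\dot w = \epsilon\,(w_\infty(v - v_0) + w_0 - w),$$
with $w_\infty(x) = 6/(1+e^{-x})$, reproduces the geometry of the switch in
a form where everything is closed-form. The $v$-nullcline
$w^2 = v - v^3/3 + I$ pinches into a self-intersection at $(v, w) = (-1, 0)$
when $I = 2/3$: the balance condition (vanishing cross-derivative product)
forces $w = 0$, the singularity condition forces $1 - v^2 = 0$, and the
self-intersecting branch point is the one at $v = -1$ where the cubic has a
double root. `planar_tc_point()` returns $(v^*, w^*, I^*, w_0^*) =
(-1, 0, 2/3, -w_\infty(-1 - v_0))$. The sigmoid's proportions (amplitude 6,
unit gain, $v_0 = 0$) were chosen so that its rise spans the whole lasso of
the $v$-nullcline: that keeps the phase portrait at three or fewer
equilibria in the physiological window and yields the canonical pair of
portraits — a single stable rest at $w > 0$ on the restorative side of
$w_0^*$, and rest ($w < 0$) + saddle + unstable focus on the regenerative
side. One honest limitation: in this vector field the depolarized attractor
that coexists with the rest deeper on the regenerative side is a stable
plateau state rather than a spiking limit cycle — spirals leaving the
unstable focus land on the resting branch instead of closing into a cycle.
The pulse-switchable two-attractor coexistence (present beyond the critical
offset, absent before it) is what `planar_bistability_test()` asserts; the
full rest-versus-spiking form of the bistability is exercised on the
conductance-based models, where it does occur.

**Synthetic generator.** `random_model()` draws leak + fast-activation
(sodium-like) channels plus slow gates constructed to have the requested
feedback sign across the −80..−40 mV operating band: restorative gates are
either delayed-rectifier-like (activation on an outward current,
$E \in [-110, -90]$) or transient-inactivation-like (inactivation on an
inward current, $E \in [20, 60]$); regenerative gates are calcium-like
(activation on an inward current, $E \in [0, 60]$). Boltzmann parameters:
$V_{1/2} \in [-70, -20]$ mV, $|k| \in [3, 15]$ mV, $\bar g \in [0.1, 10]$
mS/cm²; fast $\tau \in [0.1, 1]$ ms and slow $\tau \in [3, 10]$ ms,
matching the 5–10× separation between the two families. Candidates are
rejection-sampled until the declared signs hold across the band and a
stable equilibrium exists in $[-100, 0]$ mV; generation is deterministic in
the seed and leaves the global RNG untouched. What these fixtures emulate
is the algebraic structure of real models — arrowhead coupling, sigmoid
kinetics, mixed feedback signs; what they do not emulate is correlated
channel kinetics, multi-gate channels with shared voltage sensors, or
calcium dynamics, so green property tests certify the detection machinery,
not any particular biological model.

## Numerical choices and degenerate inputs

* Fixed-point search: sign-change bracketing on a 400-point grid over
  $[-100, 20]$ mV by default, bisection to $10^{-12}$, Newton polish with
  the exact reduced slope; duplicate roots merged within $10^{-6}$ mV;
  residuals held below $10^{-9}(1 + |I_{app}|)$. Non-converged brackets
  warn, never vanish silently.
* Away from steady state the gate rows of the Jacobian include the
  $\tau'(V)$ correction $(x_\infty - x)\tau'/\tau^2$, so the matrix is the
  true derivative of the RHS everywhere (the finite-difference oracle in
  the suite checks it at $10^{-6}$ relative); at equilibria the correction
  vanishes and the familiar $x_\infty'/\tau$ form is recovered.
* Problem sizes in the default test run were chosen to exercise every code
  path at full tolerance: the identity sweeps use 100 seeded models × 20
  voltages; the solver/oracle comparison uses the squid axon plus 25
  seeded one-regenerative-gate models with a 2000-point dense-grid
  bisection oracle; simulations use 400–700 ms protocols.
* Ties and multiplicity: when several transcritical roots exist all are
  returned ordered by $V^*$, and the command-line tool marks as primary
  the root nearest the model's nominal resting potential.

## Known limitations

Single-compartment deterministic models only; calcium concentrations enter
only as frozen auxiliaries; no limit-cycle continuation — periodic
attractors are characterized by direct simulation, so saddle-homoclinic
and SNIC curves are out of reach; Hopf positions (unlike the transcritical
and saddle-node ones) depend on the declared time constants; and the static
archetype table can disagree with the dynamic sign for particular kinetic
parameterizations of a channel subtype, which raises a warning rather than
an error by design.
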