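# tcswitch

Neurons with the same channel repertoire can express two qualitatively
different kinds of excitability. *Restorative* excitability is the textbook
kind: the resting state sits in a region where the slow gating variables
push back against voltage perturbations, spikes are all-or-none and onset is
fast. *Regenerative* excitability is marked by spike latency, plateau
oscillations, afterdepolarizations, and the robust coexistence of a
hyperpolarized resting state with a spiking attractor at the same applied
current. `tcswitch` detects the boundary between the two regimes in
arbitrary conductance-based models and quantifies everything on both sides
of it.

The package is aimed at computational neuroscientists who work with
Hodgkin–Huxley-style models

```
C dV/dt = I_app − Σ_ion ḡ_ion · Π x^p · (V − E_ion)
  dx/dt = (x_∞(V) − x) / τ_x(V)
```

and want a principled answer to "which parameter change switches this model's
excitability type, and at what value?".

## The balance equation

Group the gating variables by timescale: fast (spike upstroke), slow (spike
initiation and downstroke), ultraslow (adaptation; frozen as parameters).
Each slow gate `x_s` carries a voltage-feedback weight at an operating point

```
w_s(V) = (∂F/∂x_s) · (dx_s,∞/dV)        [mS/cm²],   F = I_app − Σ I_ion
```

negative for restorative gates (negative feedback), positive for
regenerative ones. The model's type at rest is the sign of the summed
weights, the **slow balance** `B(V) = Σ_s w_s(V)`. The switch between types
is pinned by two algebraic conditions solved simultaneously in the voltage
and one bifurcation parameter λ (a maximal conductance, a reversal
potential, or a frozen adaptation value):

* **balance**: `B(V*, λ*) = 0`
* **fast-subsystem singularity**: `s_fast(V*, λ*) = ∂F/∂V + Σ_fast w_f = 0`

Together they force the unit-τ Jacobian determinant to vanish, and the
corresponding bifurcation is a **transcritical point (TC)**: two equilibrium
branches cross and exchange stability. Crucially, neither condition involves
a time constant, so the detected point is exact regardless of the model's
kinetics. An affine reparametrization of the applied current,
`I_app(λ) = Σ I_ion(V*, x_∞(V*); λ)`, keeps `V*` an equilibrium along the
whole sweep so that the switch reflects a change in membrane dynamics, not
in net current.

## What the package provides

* model construction (`conductance_model()`, `channel()`,
  `gate_boltzmann()`, `gate_alphabeta()`) and JSON/YAML model files
  (`load_model()`, `write_model()`);
* fixed points, arrowhead Jacobians, eigenvalues, reduced slopes
  (`fixed_points()`, `model_jacobian()`, `reduced_slope()`);
* classification (`feedback_weight()`, `slow_balance()`,
  `excitability_at_rest()`, `feedback_report()`, static archetype lookup
  `table1_class()`);
* transcritical detection (`solve_tc()`, `i_app_at_tc()`,
  `affine_current()`, `verify_tc()`);
* pseudo-arclength continuation with saddle-node / Hopf / transcritical
  event detection (`continue_fixed_points()`, `bifurcation_diagram()`);
* stiff simulation and signature quantification (`integrate_model()`,
  `detect_spikes()`, `signature_report()`, `bistability_test()`);
* built-in fixtures: the squid-axon Hodgkin–Huxley model (`build_hh()`), a
  planar caricature with a closed-form transcritical point
  (`planar_model()`, `planar_tc_point()`), and a seeded synthetic-model
  generator (`random_model()`);
* `autoplot()` methods for branches, traces and feedback reports, and
  broom-style `tidy()`/`glance()` for solved objects;
* a thin command-line wrapper (`inst/cli/tcswitch.R`) with subcommands
  `classify`, `find-tc`, `continue`, `simulate`, `fixtures`.

## Worked example: the squid axon and its potassium reversal

The classic Hodgkin–Huxley model is restorative under physiological
conditions — both slow gates (sodium inactivation `h`, potassium activation
`n`) provide negative feedback — but raising the potassium reversal `E_K`
(high extracellular potassium) turns the `n` feedback positive:

```r
library(tcswitch)
hh <- build_hh()
glance(feedback_report(hh, fixed_points(hh)$V))
#> # A tibble: 1 × 5
#>       V total_regenerative total_restorative balance label
#>   <dbl>              <dbl>             <dbl>   <dbl> <chr>
#> 1 -65.0                  0            -0.921  -0.921 restorative

tc <- solve_tc(hh, hh_ek_param(), V_range = c(-90, 0))
tidy(tc)[1, ]
#> # A tibble: 1 × 6
#>   V_star lambda_star  I_TC res_balance res_fast verified
#>    <dbl>       <dbl> <dbl>       <dbl>    <dbl> <lgl>
#> 1  -61.8       -59.9 -6.37   -3.79e-13 6.52e-13 TRUE
```

The balance breaks at `E_K* ≈ −59.9 mV` with critical voltage
`V* ≈ −61.8 mV`; the applied current that makes `V*` an equilibrium there is
`I_TC ≈ −6.4 µA/cm²`. Note `E_K* > V*`: the potassium driving force must
invert, exactly the physiological condition for the switch. Continuing the
equilibria against `E_K` with the affine current law installed reproduces
the expected diagram — a saddle-node (birth of the regenerative resting
state), the transcritical crossing at `E_K*`, then a Hopf:

```r
sw <- sweep_bif_param(hh, hh_ek_param(), tc[1, ], range = c(-90, -20))
dg <- bifurcation_diagram(sw)
dg$events[, c("type", "param", "V")]
#>   type  param     V
#> 1 SN    -60.3 -66.8
#> 2 TC    -59.9 -61.8
#> 3 HB    -59.7 -60.9
#> 4 HB    -48.2 -41.5
```

On the far side of the crossing the model is regenerative and bistable: a
depolarizing pulse latches it into tonic spiking, a hyperpolarizing pulse
switches it back, and first-spike latency exceeds the restorative case at
matched drive (`bistability_test()`, `signature_report()`).

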