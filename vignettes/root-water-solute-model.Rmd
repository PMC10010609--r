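---
title: "Coupled water and solute transport on root system architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled water and solute transport on root system architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootflow)
```

## The problem

A de-topped maize primary root in a pressure chamber exudes xylem sap at a
rate `Jv` that depends on the pressure `Pe` applied to the bathing solution.
Two protocols probe its transport machinery: a pressure sweep, `Jv(P)`, and
the cut-and-flow protocol, in which the root system is excised stepwise from
the tip while `Jv` is recorded at a fixed operating pressure. Inverting a
transport model against both series yields the radial hydraulic conductivity
`k`, the axial conductance profile `K(x)` of the xylem, and — once solutes
are modelled — the active solute uptake rate `Js*` and solute permeability
`Ps` of the root tissues.

A purely hydraulic tree model cannot explain three robust observations:
spontaneous exudation at atmospheric pressure, the curvature of `Jv(P)` at
low pressure, and sustained negative flow in roots equilibrated with a
PEG-8000 (water-deficit) medium. All three require osmotic driving forces
maintained by solute transport, which is what this package adds to the
classical hydraulic-architecture approach.

## The model

The root system architecture (RSA) is a rooted tree of axes (one primary,
first-order laterals), discretized into cylindrical representative
elementary volumes (REVs) of length `l` (default 1 mm, of the order of the
primary root diameter) and diameter equal to the root diameter. Each REV
exchanges water radially with the bath and conducts sap axially toward the
base.

Radial water flux into the xylem of a REV of lateral surface `S = pi d l`:

    j = k (Pe - P - pi_peg_ext + pi_peg - sigma R T (Ce - C)) S

with `P` and `C` the local xylem pressure and solute concentration, `Ce`
the bath concentration, and `pi_peg` the osmotic pressure contributed by
PEG. PEG 8000 is non-permeant: its osmotic terms carry a reflection
coefficient of 1 (they are not multiplied by `sigma`), and PEG can enter
the xylem only through open cut faces. The lumped nutrient solute has an
effective reflection coefficient `sigma = 0.85` by default, a value
reported for nutrients on maize root systems.

Axial sap flow between a REV and its parent follows a Hagen-Poiseuille law,

    J = K(mu) dP / l,      K(mu) = K_ref / mu,

with `K_ref` the conductance at the reference sap viscosity of 1 mPa s and
`mu` the local viscosity in mPa s. `K_ref` varies with the distance to the
root tip as a piecewise-linear profile (`K_knots`), clamped constant beyond
the end knots.

Radial solute flux combines a constant active uptake and a passive leak:

    js = (Js* - Ps (C - Ce)) S

The leak term is not optional physics: with a steady *negative* sap flow
(observed in PEG roots) and active uptake only, solute mass would
accumulate without bound in the xylem; `Ps > 0` is what makes a steady
state exist. The solver raises an explicit "unbounded accumulation" error
when asked for a steady state with `Ps = 0` and a stagnant REV under
active uptake.

Solutes and PEG are advected along the xylem (`Js = J C`, `Jpeg = J
C_peg`); there is no axial diffusion term, consistent with the
advection-dominated regime of xylem transport.

### PEG physics

The water potential of a PEG 8000 solution does not follow Van't Hoff's
law. The package uses the standard empirical calibration, quadratic in
concentration and linear in temperature (with concentration in kg PEG per
kg water, numerically identified with kg l^-1 at working dilutions):
`Psi(0.150, 25 C) = -0.302` MPa, so that PEG added to the control solution
(-0.034 MPa) gives the -0.336 MPa water-deficit medium. Viscosity follows
an exponential fit to published viscosimetry anchored at pure water:
`mu(w) = -17.4 + 18.4 exp(w / 0.279)` mPa s, giving 14 mPa s at
150 g l^-1. Both laws are calibrated up to 0.25 kg l^-1; inside the solver
their argument is capped there so that numerical transients cannot blow up
the exponential.

## Boundary conditions and numerical scheme

Boundary conditions: `P = 0` (atmospheric, relative) at the basal face,
sealed apices (zero axial flux), and `P = Pe` with advective exchange of
bath composition at every open cut face.

The steady state is computed by a fixed-point iteration that alternates two
exact linear solves on the tree:

1. **Pressure.** For frozen concentration fields, nodal water balance gives
   a symmetric positive-definite system with tree sparsity, solved by a
   fill-in-free elimination in post-order (children before parents) —
   an O(n) direct solve implemented in C++.
2. **Advection.** For the resulting flow field, donor-cell (upwind)
   steady-state balances for `C` and `C_peg` give an M-matrix with the same
   tree sparsity, solved by the same elimination. Upwinding is the only
   scheme that guarantees non-negative concentrations on a tree with flow
   reversals, and reversed flow is a headline regime here.

Concentration updates are under-relaxed with a nominal factor of 0.8.
Each node additionally carries its own step factor, halved whenever the
node's update direction flips between iterations and recovered (times 1.25,
capped at the nominal factor) otherwise. This quenches the donor-cell limit
cycles that otherwise appear at REVs sitting exactly at an osmotic balance
point (the upwind donor switches sides as the tiny local flow changes
sign). Convergence is declared when the applied relative state changes of
`P`, `C`, `C_peg` and the basal outflow all fall below `tol` (default
1e-8), with a cap of 500 iterations; non-convergence is reported on the
returned state together with the residual history. The converged fields are
mutually consistent to `tol`; each field separately satisfies its own
balance equations to linear-solver precision, which is why the
conservation audits close to ~1e-12 regardless of `tol`.

Two further numerical choices matter in PEG baths:

* **Edge viscosity** is taken from the upstream REV of each edge (upwind,
  using the previous iterate's flow direction), and from the bath for
  inflowing cut faces.
* **Stagnant backwaters.** After a cut, the apical part of a severed
  lateral can carry a throughflow orders of magnitude below the dominant
  flow while losing water radially. PEG entering such a region has no
  outflow path: physically its concentration rises until viscosity chokes
  the feeding flow. REVs with throughflow below `stagnation_rel` (default
  1e-3) of the dominant flow are therefore treated as non-transporting for
  PEG (their PEG content is held fixed), which emulates the choked limit
  and removes a numerically pathological degree of freedom whose value has
  no measurable effect on the basal outflow (relative effect ~1e-4 in our
  tests).

Under reversed basal flow the fluid re-entering the root carries, by
default, the basal REV's own concentrations (a zero-gradient condition,
treated implicitly in the matrix); `basal_inflow = "bath"` switches to bath
composition. The choice is isolated behind `solve_control()` because the
experimental literature does not determine it.

## The osmometer reduction

Collapsing the whole architecture to one semi-permeable barrier of area
`S_tot` separating the bath from a well-mixed interior at relative pressure
0 gives the classical two-compartment osmometer. Eliminating `Jv` from the
water and solute balances leaves a quadratic in `C` whose coefficients have
exactly one sign change, hence exactly one non-negative root — the closed
form implemented in `osmometer_steady_state()`. It has three uses: an
independent oracle for the tree solver (a one-REV architecture must
reproduce it to 1e-8); the source of exact reference points (at zero flow,
`C - Ce = Js*/Ps` and the pressure offset is `sigma R T Js*/Ps`, 0.2106 MPa
at the default parameter ratios); and the baseline for quantifying what is
lost by ignoring architecture (`compare_with_rsa()`): in high-flow roots
the sap is progressively diluted toward the base, a gradient the
compartment model cannot represent, so its fitted `k` comes out low.

## Inverse estimation

The objective is the pooled sum of squared flow errors over both protocol
series, `F = sum (Jv_obs - Jv_model)^2`, in ul^2 s^-2. The `K` profile is
parameterized with one knot per cut, at the blade distances to the tip, so
each cut-and-flow point constrains essentially one knot; with uniform `k`,
`Js*`, `Ps` a nine-cut experiment gives the maximal 12-parameter problem.

The workflow has three stages, each a Levenberg-Marquardt minimization over
log-transformed parameters (positivity by construction), warm-starting
every steady-state solve from the previous evaluation at that protocol
point:

1. `K` profile and `k` on the cut-and-flow data alone, with solute
   transport off and the osmotic term frozen at a constant offset estimated
   from the pressure intercept of the linear part of `Jv(P)`;
2. `k`, `Js*`, `Ps` on the `Jv(P)` data with the full model, `K` fixed;
3. joint refinement of all parameters on both series.

First guesses: `k = 1e-7` m s^-1 MPa^-1, `Js* = 1e-7` mol m^-2 s^-1,
`Ps = 1e-9` m s^-1, and a `K` profile spanning 1e-12 to 1e-10
m^4 MPa^-1 s^-1 (a step at ~0.1 m, or its monotone analogue, a log-linear
ramp) — literature orders of magnitude for maize seedlings.

Two design choices were genuinely open and deserve their rationale:

* **Monotone `K` by default.** The cut-and-flow interpolation problem
  admits multiple exact solutions: we verified sawtooth-shaped knot
  profiles, with adjacent knots off by more than 100% in compensating
  directions, that reproduce the very same cut-and-flow flows to numerical
  precision and sit behind an objective ridge that traps every local
  optimizer we tried. Xylem maturation makes the physical profile
  non-decreasing away from the tip, so `fit()` parameterizes `K` as log-K
  at the first knot plus positive log-increments. This excludes the
  spurious branches; `monotone_K = FALSE` restores unconstrained knots.
* **Levenberg-Marquardt throughout.** The staged structure (which series
  constrain which parameters) is the scientific content of the workflow;
  for the numerical engine we use the canonical small-residual
  least-squares method. In side-by-side runs on clean synthetic data, a
  simplex search followed by a quasi-Newton polish needed roughly ten
  minutes per root and stalled far from the optimum, while LM converges to
  machine-level residuals in about a minute. The finite-difference Jacobian
  step (`epsfcn = 1e-6`, i.e. ~1e-3 relative steps) is kept well above the
  fixed-point truncation level so derivative estimates are not dominated by
  solver noise.

`fit_pure_hydraulic()` implements the classical simplification — osmotic
term frozen at a constant `P0`, fitted on the linear part of `Jv(P)` plus
the cut-and-flow data — to expose its bias relative to the full model, and
`sensitivity_scan()` re-fits `k` over grids of `Js*`, `Ps` and `sigma` to
show how weakly the hydraulic parameters depend on the solute ones.

## The synthetic generator and what passing tests mean

`generate_synthetic_rsa()` emulates an 11-day-old hydroponic maize seedling
root system: a single primary axis (default 0.35 m) with first-order
laterals placed by a Poisson process (default 60 m^-1, about 20 laterals)
outside a 0.02 m apical unbranched zone, lateral lengths normal
(mean 0.04 m, sd 0.015 m, truncated at 5 mm), and panel-mean diameters by
growth condition (primary 1.05/1.03 mm, laterals 0.36/0.39 mm for
control/PEG-grown plants). `default_cut_schedule()` mirrors the experiment:
a first cut of 8.3 cm, further cuts of 4.3 cm, at least 5.2 cm of root kept
— six cuts on a 0.35 m primary. `synthetic_k_profile()` draws ground-truth
conductance profiles as a jittered, monotone log-ramp from 2e-12 to 8e-11
m^4 MPa^-1 s^-1.

The generator does not emulate second-order laterals, root growth between
protocols, chamber sealing artifacts, flowmeter dynamics, or spatial
variation of `k`, `Js*`, `Ps` along the axes (the model assumes them
uniform). Parameter-recovery results on these synthetics therefore
demonstrate the correctness and identifiability of the inversion under the
model's own assumptions — not that real roots satisfy those assumptions.

## Problem sizes and numerical settings used by the test suite

Unit and invariant tests run on roots of 0.06-0.2 m with REVs of 1-2.5 mm.
The parameter-recovery study uses ten 0.35 m roots with ~20 laterals,
six cuts, the first eight steps of the standard pressure sequence, and
2 mm REVs for both data generation and fitting (the discretization-
convergence test shows halving the REV length moves `Jv` by well under 1%,
and 2 mm keeps a full ten-root study in the minutes range). The
viscosity-bias study re-fits only the `K` profile of a water-deficit root
in a PEG bath, with the viscosity coupling on versus forced to 1 mPa s, and
compares the recovered profiles knot-wise as a geometric mean ratio.

## Known limitations

* Steady state only; the ~140 s cutting transient of the experiment is not
  modelled.
* Junctions carry no extra hydraulic resistance.
* The stretched-tipward convention decides which lateral segments a blade
  removes (`lateral_rule = "own_distance"` is the alternative); real
  Petri-dish geometry is messier than either rule.
* Basal re-entry composition under reversed flow is a modelling choice,
  not a measurement.
* Transient intermediates of the fixed-point iteration are not physical;
  only the converged state is.
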