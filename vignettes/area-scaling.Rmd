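---
title: "Membrane-area scaling in multi-compartment kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-area scaling in multi-compartment kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(areakin)
```

## The modelling problem

Ordinary-differential-equation models of cellular pathways usually treat
each compartment as well stirred and express reaction velocities in
concentrations, e.g. for a reversible first-order interconversion
$S \leftrightarrow P$,

$$\nu = k_f\,[S] - k_r\,[P].$$

This is fine inside one compartment. A *trans-membrane* reaction, with
$S$ and $P$ in compartments of volumes $V_1$ and $V_2$, is different: a
decrease of $[S]$ does not produce an equal increase of $[P]$, and the
bookkeeping must be done in molar amounts ($nS = [S]\,V_1$). The
conventional fix multiplies each side's concentration rate by its
compartment volume,

$$\nu_n = V_1 k_f \frac{nS}{V_1} - V_2 k_r \frac{nP}{V_2},$$

but transport physically proceeds at the membrane: its rate is set by
the number of transporters, or — at constant transporter density — by
the interface area $A$,

$$\nu_n = A\,(k_{af}\,[S] - k_{ar}\,[P]),$$

with first-order constants $k_{af}, k_{ar}$ now carrying length/time
units (µm s⁻¹ in this package). The two conventions agree at any single
reference geometry (set $k_f = k_{af} A/V_1$, $k_r = k_{ar} A/V_2$) and
disagree as soon as volumes change relative to areas, because volume
and area scale differently with cell shape: a sphere's volume grows
like $r^3$ against a surface of $r^2$, and an elongating root epidermis
cell grows its volume linearly in length while its vertical
cell-to-cell interface $w \times d$ does not grow at all.

`areakin` makes the scaling assumption an explicit, per-reaction
property and provides the machinery to quantify its consequences:
building models under either convention (plus a merged single-pool
idealisation), simulating them, computing scaled sensitivities, and
rewriting volume-scaled SBML kinetic laws to area scaling without
changing reference behaviour.

## State variables, units, conventions

The ODE state is the vector of species **amounts**, the SBML
convention; concentrations are derived views $[S] = nS/V$. Amounts make
trans-compartment stoichiometry conserve mass by construction and avoid
the volume-ratio pitfalls of concentration-state formulations. Units
are fixed package-wide: lengths µm, areas µm², volumes µm³ (= fL),
concentrations µmol/L, time s. One amount unit is therefore
1 µM · µm³ = 10⁻²¹ mol.

Three scaling regimes are supported per reaction:

* **volume** — $\nu_n = V_1 k_f \prod [S_i] - V_2 k_r \prod [P_j]$,
  generalised mass action with each side scaled by its own
  compartment's volume;
* **area** — $\nu_n = A (k_{af} \prod [S_i] - k_{ar} \prod [P_j])$, $A$
  either a number or a named membrane interface of a compartment;
* **single** — all species share one pool whose volume is the sum of
  the member volumes; transport degenerates to interconversion and
  geometry has no effect on concentration dynamics. This tie-break
  (pool volume = sum) makes the pooled model's initial amount flux
  matchable to the two-compartment models at calibration.

Imported SBML kinetic laws are carried as opaque amount-rate
expressions (an escape hatch that also covers saturating laws);
hand-built models use mass action, which is all the analyses here need.

## Compartment geometry

Nuclei are treated as perfect spheres and a measured nuclear
cross-section as the great-circle section, $r = \sqrt{A_{cs}/\pi}$ —
the only reading under which the published HeLa geometry table is
internally consistent. Volume, surface and cross-section then satisfy
$\mathrm{surface} = 4 \times \mathrm{cross\ section}$ exactly. The
regenerated table agrees with the published one to within 0.2%
relative; the residual (e.g. exact 800 vs printed 800.23) reflects the
original authors' unstated intermediate rounding, which we deliberately
do not try to replicate — the package computes exactly and the tests
assert the 0.2% band.

Root epidermis cells are cuboids $L \times w \times d$ with the
vertical interface $w \cdot d$ shared between axial neighbours. Width
and depth default to 5 µm, constant across developmental zones —
root cells grow almost exclusively in length, which is precisely what
makes them the ideal stress test for scaling assumptions.

## The root transport comparison

The experiment simulates reversible transport $X_1 \leftrightarrow X_2$
between two adjacent epidermis cells at four positions along the root
axis, with zone lengths 8, 30, 90 and 220 µm (the printed extremes are
8 and 220 µm; the intermediate values are package defaults and
config-overridable). Scenario 1 pairs two equal meristematic cells;
scenarios 2–4 pair each older zone's cell (upstream, carrying the
initial 1 µM of $X_1$) with the adjacent younger zone's cell, so total
cell size increases strictly along the series.

Making scenario 1 the *symmetric* pair is a deliberate design choice.
Calibration converts the area constants to volume-mode constants via
$k_f = k_{af} A / V_1$, $k_r = k_{ar} A / V_2$, which renders all three
implementations literally identical at the calibration geometry — the
pooled model included, and for both species, not just the tracked one.
With an asymmetric calibration pair, $k_f \neq k_r$ even for symmetric
transport ($k_{af} = k_{ar}$), and the volume model's equilibrium
concentration ratio would carry a constant $V_{1,\mathrm{cal}} /
V_{2,\mathrm{cal}}$ factor instead of the clean $V_2/V_1$ that the
mass-action equilibrium of the volume-scaled law predicts. Since the
actual cell dimensions behind the published figure are in unprinted
supplementary tables, the package picks the internally consistent
variant and treats the three qualitative signatures as the reproducible
content:

1. **area scaling** — time to 95% equilibrium grows strictly with cell
   size (relaxation rate $\lambda = A(k_{af}/V_1 + k_{ar}/V_2)$ falls as
   volumes grow at fixed $A$), and equilibrium concentrations
   equalise ($[X_1]_{eq} = [X_2]_{eq}$ for $k_{af}=k_{ar}$) while
   amounts split $V_1 : V_2$;
2. **single compartment** — concentration trajectories are identical
   across scenarios (the pool volume cancels);
3. **volume scaling** — $\lambda = k_f + k_r$ independent of geometry,
   while the equilibrium concentration ratio shifts to $V_2/V_1$.

These signatures hold for any positive rate constants and any
increasing geometry series, which the property tests exercise over
random draws. Default transport constants are $k_{af} = k_{ar} =
0.1\ \mu\mathrm{m\,s^{-1}}$ — a typical passive-permeability scale
that relaxes scenario 1 on the order of two minutes; symmetric
constants keep the area model's equilibrium concentration-equalising.

```{r root, eval = FALSE}
cmp <- run_transport_comparison(make_root_series(), kaf = 0.1)
cmp$deltas  # time-to-equilibrium ratios vs scenario 1
```

## Numerics

Integration uses LSODA (stiff/non-stiff switching) via deSolve on a
dense uniform grid, defaults `rtol = 1e-8`, `atol = 1e-12` (amount
units). Analysis horizons are set to $20/\lambda$ from the closed-form
relaxation-rate estimate, leaving an $e^{-20} \approx 2\times10^{-9}$
residual so that equilibrium values read off the final point are good
to ~1e-9; if a trajectory is not equilibrated (final 5% of points
varying by more than 0.1% relative), `equilibrium_metrics()` refuses
with advice rather than reporting a drifting "equilibrium", and the
comparison driver extends the horizon automatically. Time-to-fraction
uses $f = 0.95$ by default — reported alongside results since "time to
equilibrium" has no canonical numeric definition. Peaks are global
maxima over the dense grid (≥ 1000 points for peak-based metrics) with
earliest-time tie-break. Steady states come from long integration
followed by damped Newton polishing on a finite-difference Jacobian;
conservation relations make the Jacobian singular, so the step is
solved in the least-squares sense, which only moves within the
reachable stoichiometric subspace.

Scaled sensitivities $(p/y)\,\partial y/\partial p$ use central
differences under multiplicative perturbation with $\delta = 10^{-3}$:
second-order accurate, exact for linear outputs, and convergent at
$O(\delta^2)$ (Richardson-checked in the tests). Parameters must be
strictly positive; a zero reference output makes the coefficient
undefined and is reported as such. A *group* of parameters can be
perturbed concomitantly by one factor — this is how the robustness of
the nucleocytoplasmic gradient is probed: the steady-state gradient of
the shuttle template is $k_{in}/k_{out}$, so the combined coefficient
vanishes while each single-rate coefficient is ±1.

## SBML rescaling

The SBML layer is deliberately minimal: Level 2/3 core with
compartments, species, parameters (global and reaction-local),
reactions with MathML kinetic laws over `+ - * / ^ exp ln log`, and
assignment rules. Events, rate and algebraic rules, function
definitions, constraints and initial assignments raise an explicit
unsupported-feature error naming the construct. Species flagged
`hasOnlySubstanceUnits` enter laws as amounts; boundary/constant
species keep fixed amounts.

`rescale_to_area()` rewrites a volume-scaled law to area scaling only
when it *structurally* factors, at the top multiplicative level, as
(compartment size) × (expression) — a `ci` naming a declared
compartment, or a literal equal to a declared size within 1e-9
relative. Which compartment's volume the law used is taken from the
matched factor, never assumed. The factor is replaced by a new area
parameter (unit annotation µm²; plain parameter rather than a 2-D
compartment, for broad tool compatibility) and the law is multiplied by
$V_{ref}/A_{ref}$ so the amount rate is unchanged at the reference
geometry. The correction is applied to a rate constant found at the
top multiplicative level of the remainder (adjusted through a
reaction-local override, since locals shadow globals in SBML — a
shared global is never mutated); if the remainder is a sum, as in
$V(k_f[S]-k_r[P])$, a synthetic local scaling factor is introduced
instead, because adjusting a constant inside one term of a sum would
silently change the law. Two-volume laws
($V_1 k_f [S] - V_2 k_r [P]$) do not factor and are refused.
`rescale_to_volume()` inverts the transformation exactly, recovering
the original constants to machine precision.

Geometry what-if scenarios multiply compartment sizes (species
concentrations preserved) and area parameters independently:
`radius_scenario(f)` applies $f^3$ to volumes and $f^2$ to areas (a
uniform radius change), `area_scenario(f)` changes areas only — which
by construction cannot affect a volume-scaled model, a useful negative
control that the tests assert bit-identically.

## What the fixtures emulate — and what they do not

The generator reproduces the *structure* of the study inputs: the
root-cell length series with constant width/depth, the HeLa
cell/nucleus geometry table regenerated from its measured inputs, toy
two-compartment SBML documents with one volume-scaled transport
reaction (seed-deterministic to the byte), and a minimal
nucleocytoplasmic shuttle. They do not emulate the full published
case-study models (RanGTP shuttling, TGF-β/Smad signalling): those are
multi-reaction networks with saturating kinetics whose SBML files live
in a model repository and are not bundled or downloaded here. Passing
tests therefore demonstrate the correctness of the geometry, the
scaling algebra, the integrator agreement with closed forms, and the
rescaling machinery — not quantitative reproduction of any published
case-study trajectory. Supplying such a model file locally to
`rescale_report()` runs the identical pipeline on it.

Problem sizes used by the test-suite and the acceptance script — 100–200
random two-compartment models for the oracle sweep, 40–60 for rate
recovery, a handful of seeds for document-level checks — were chosen as
comfortably sufficient to pin down the deterministic quantities
involved.

## Known limitations

* Mass action plus opaque expressions only; no dedicated builders for
  saturating rate laws.
* Geometry is idealised (spheres, cuboids, direct value tables); no
  image-derived or mesh geometry, and multinucleated or irregular
  nuclei are representable only through their effect on the area
  value.
* The SBML subset excludes events and non-assignment rules; documents
  using them must be simplified upstream.
* Deterministic ODE semantics only — no stochastic or spatial
  formalisms.
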