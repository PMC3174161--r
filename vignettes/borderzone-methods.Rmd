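---
title: "Methods: spiral and scroll waves in a recovering ischaemic border zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiral and scroll waves in a recovering ischaemic border zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`borderzone` simulates electrical activity in a network of neonatal
cardiac myocytes arranged on a rectangular grid (4 neighbours in 2D, 6 in
3D) and coupled by Ohmic resistances.  Each cell follows the
Beeler-Reuter-Pumir (BRP) kinetics: the classic eight-variable
Beeler-Reuter ventricular model (voltage `V`, intracellular calcium `Ca`,
gates `m, h, j, d, f, x1`) with three neonatal modifications:

* fast inward maximum permeability reduced to 60% of the adult value
  (`gNa_max = 2.4` vs 4),
* slow inward maximum permeability reduced to 50% (`gs_max = 0.045`
  vs 0.09),
* the inward rectifier `i_K1` suppressed to a baseline fraction
  `k_K1_base`, and further by the *excitability parameter*
  `alpha in [0, 1)`:

  `i_K1 -> k_K1_base * (1 - alpha) * i_K1(BR)`.

Raising `alpha` removes repolarizing current: the cell becomes more
excitable, and above a threshold it fires spontaneously (single-cell
automaticity).  With the default `k_K1_base = 0.5`, the single-cell
automaticity threshold lies between `alpha = 0.65` and `0.70`.  Only the
product `k_K1_base * (1 - alpha)` enters the dynamics, so the choice of
`k_K1_base` fixes the labelling of the `alpha` axis rather than the model
family; 0.5 was chosen once and is configurable.

The voltage coupling between neighbouring cells is a divergence-form
discrete Laplacian with interface conductance `(D_i + D_j)/2` when both
sides have positive diffusivity and zero otherwise, so a `D = 0` cell is
fully isolated; outer boundaries are no-flux.  The grid sum of the
coupling operator vanishes identically (conservation).

Integration is forward-Euler for `V` and `Ca` with Rush-Larsen
exponential updates for the six gates (gates stay in `[0, 1]` for any
`dt`).  The tissue kernel is compiled (Rcpp) with voltage-indexed rate
tables (4001 points over `[-120, 80]` mV, linear interpolation).  Any
voltage excursion outside `[-120, 80]` mV aborts the run with the step
and cell location.

### Units and defaults

Lengths in mm, time in ms, voltage in mV; currents in the original
Beeler-Reuter unit system with unit membrane capacitance.  The cell size
defaults to `h = 0.1 mm`; positions are reported in both mm and cell
units.  The default time step is `dt = 0.05` ms for single cells (the
action-potential peak moves < 0.5 mV when it is halved) and `dt = 0.1`
ms for tissue, which is well inside the diffusive stability bound
`h^2 / (2 dim D)` at the default coupling.

The printed values of the original protocol constants (layer
diffusivities, excitability limits, border width and speeds, box sizes)
are not available in the source text; the bundled defaults encode this
package's desk-scale working point, chosen once:

* well-coupled diffusivity `D0 = 0.0025 mm^2/ms` (coupling
  `D0/h^2 = 0.25 /ms`), uncoupled bottom layer `Dmin = 0`;
* background excitability for spiral studies `alpha = 0.65`;
* border width 2 mm, moving at `|u| ~ 0.002 mm/ms` by default.

## The border zone

Diffusivity and excitability vary across the slab (coordinate `y`) as
clamped ramps between moving limits `y1(t) = y1_0 + u t` and
`y2(t) = y2_0 + u t` (piecewise-linear by default, smoothstep as an
option).  The excitability ramp is displaced *below* the coupling ramp
by `alpha_shift` (default: one border width): excitability recovers
before coupling does, so the slab stacks a quiescent uncoupled bottom
layer (low `alpha`, `D = 0`), a transitional band of high excitability
and still-weak coupling — the habitat of ectopic sources and
mini-re-entry — and a well-coupled excitable top layer.  With the two
ramps coincident (zero shift) no such band exists and the protocols stay
silent, which is why the shift is a structural default, not a tuning
knob.  Frozen per-cell Gaussian heterogeneity
`alpha_cell = profile + nu * xi`, `xi ~ N(0,1)` i.i.d., clamped to
`[0, 1)`, models intrinsic myocyte variability; cells whose `alpha_cell`
crosses the local automaticity threshold become ectopic sources, which
is the seed of all spontaneous activity in the protocols.  Heterogeneity
applies to `alpha` only, not to `D`.

## The working-point rotor

At the default working point (`alpha = 0.65`, coupling `0.25 /ms`) a
cross-field (S1-S2) stimulus initiates a single stable spiral.  This
rotor is a slow, large-core vortex: the detected tip (intersection of
the `V = -30` mV and `f = 0.5` isolines) moves around a near-circular
orbit of radius ~5 cells with a period of ~1.9 s, and any probe cell is
re-excited once per orbit.  The orbit is deterministic.  Two
consequences shape the analysis design:

* *Rotation counts are expensive*: five rotations take ~10 s of
  simulated time, which sets the duration of the rigidity and drift
  measurements.
* *Drift must be measured differentially*: the net drift induced by a
  small perturbation is much slower than the orbital tip motion, so all
  specific forces are estimated from the difference between a perturbed
  trajectory and an unperturbed control started from the same state
  (both runs are deterministic, so the orbital component cancels to
  first order).  The public `drift_velocity()` implements the
  sliding-period-average estimator and is validated on constructed
  cycloids; the force-estimation pipeline uses the control-differencing
  estimator internally.

## Specific forces

All forces are estimated empirically from direct simulations (the
adjoint response-function machinery is out of scope by design):

* **Curvature-equivalent / electrophoretic force `b2`.**  An advection
  term `E dV/dx` (applied to `V` only, central differences) induces a
  drift `v(E) = b2 E`; the complex slope through the origin over a small
  symmetric set of `E` values gives `b2`, and the filament-motion
  coefficient is `B = -b2` (real part = filament tension, imaginary
  part = binormal drift).  At the working point `b2 ~ -0.2 + 0.4i`:
  the tension component is smaller than the binormal component, and the
  lateral drift dominates.  `|E|` must stay at or below ~0.002 mm/ms:
  larger advection breaks the wave.
* **Excitability-gradient force.**  A shallow linear ramp
  `alpha(x) = alpha0 + g x` induces a drift whose longitudinal component
  is negative, i.e. directed towards *lower* excitability, at all tested
  working points.
* **Disk-inhomogeneity curve.**  A disk of radius `R0` and contrast
  `delta_alpha` at distance `d` from the core induces a drift resolved
  into radial (positive = towards the disk centre) and azimuthal
  (positive = clockwise) components per unit contrast.  The radial
  component per unit contrast is negative at all probed distances, so a
  lowered-excitability disk attracts the spiral and a raised one repels
  it; the magnitude falls roughly 300-fold between `d = 1` and
  `d = 3.5` mm (exponential-type decay to the noise floor).

## The asymptotic drift ODE

With the origin at the disk centre, the spiral centre `R = r e^{i theta}`
obeys

`dR/dt = hg e^{i gamma} - delta_alpha (F_r(r) + i F_theta(r)) e^{i theta}`

whose polar components give radial and angular balance.  Equilibria are
radii where `|delta_alpha| sqrt(F_r^2 + F_theta^2) = hg` with the angle
fixed by the complex force balance (note: the balance determines one
angle per admissible radius; the familiar "at least two equilibria"
arise from the rise-and-decay shape of the force curve giving two radius
roots).  No equilibrium can exist when `hg` exceeds the tear-off
threshold `max_d |delta_alpha| sqrt(F_r^2 + F_theta^2)`.

An equilibrium is linearly stable iff, at its radius,

1. `d/dr (F_r^2 + F_theta^2) > 0` (independent of the sign of the
   contrast), and
2. `sign(delta_alpha) d/dr (r F_r) > 0`.

These conditions were re-derived from the planar system (trace/
determinant of its Jacobian, which is
`[[-a', b], [-b'/r, -a/r]]` with `a = delta_alpha F_r`,
`b = delta_alpha F_theta` at the equilibrium) and are cross-checked in
every call against the numerically computed Jacobian eigenvalues;
eigenvalues with real part within `1e-8` of zero are reported as
marginal, never silently classified.  With the BRP-shaped curves
(rise-and-decay, constant-sign radial part) stable equilibria exist only
for attracting disks, as the graphical argument predicts.

Force-curve samples are interpolated with monotone (Fritsch-Carlson)
cubics and set to zero beyond the last sample, honouring the exponential
decay of the response.  The ODE integrator is an adaptive Cash-Karp
Runge-Kutta (no ODE-solver package is available in the target
environment), with events for equilibrium capture and escape from the
sampled range.

## Pinning experiments

In direct simulations the dragging force is supplied by the advection
term (`E ~ 0.0007`, well below the tear-off value of the probe disks)
and disks are placed relative to the measured free-drift direction:

* an *attracting* disk (`delta_alpha = -0.5`, `R0 = 0.5` mm) captures
  the spiral, which settles permanently just down-force ("behind") of
  the disk centre;
* a single *repelling* disk (`delta_alpha = +0.3`) slows the approach,
  deflects the core around one side (the side is set by the chirality),
  and the drift resumes — net progress is preserved;
* a second repelling disk placed on that detour route blocks it; the
  spiral is held with bounded net progress — the drift stops.

The classification operates on the orbit-averaged path (rolling mean
over one orbit period) using progress along the drag direction and
windowed speeds; raw tip speed is dominated by the orbital motion and
would misclassify everything as free drift.

## Discreteness

Lattice discreteness acts like a pinning potential on the core.  At
fixed weak drive, lowering the coupling makes the longitudinal (tension)
drift component shrink markedly before the lateral one — the measured
ladder at `E = 0.0005` shows the longitudinal component falling by a
third between couplings 0.25 and 0.03 /ms while the lateral component
stays constant.  Below coupling ~0.02 /ms propagation fails altogether
(the quiescent-uncoupled regime), which bounds how far the ladder can be
pushed: in this model the *complete* arrest of both components was not
observed before propagation failure — the longitudinal component
freezes, the lateral one persists, and the test suite records exactly
this (see the acceptance notes).

## What the synthetic world does and does not establish

The generator produces: analytic phase fields (linear planes, rigid
Archimedean spirals, extruded spirals, scroll-ring torus phases) for
detector tests with known singularity geometry; frozen Gaussian
heterogeneity fields; and the full moving-border protocols at desk
scale (boxes of order 10^4 cells instead of the original large grids).
Desk scale preserves the mechanisms — ectopy from heterogeneity in the
weakly coupled band, wavebreak, drift, pinning, escape — but not any
quantitative rates of the original figures; all quantitative acceptance
checks are therefore property-based (signs, orderings, monotonicity,
conservation, convergence), not value reproduction.  Boundary effects
are non-negligible in desk-scale boxes; control-differencing absorbs
most of them, and the remaining deviation is part of the reported
uncertainties.

## Numerical choices

* CFL guard: tissue stepping refuses to start when
  `dt > 0.9 h^2 / (2 dim max D)`.
* Tip detection: Newton iteration on the bilinear two-isoline system per
  candidate square; exact on piecewise-linear fields; candidates
  deduplicated at quarter-cell resolution.  Default isovalues
  `V = -30 mV` (mid-upstroke of the working-point action potential,
  rest ~-82 mV, peak ~+27 mV) and `f = 0.5`.
* Track linking: greedy nearest-neighbour with a 2-cell jump bound per
  sample.
* Filament linking: per-voxel-face tip detection, voxels with exactly
  two face crossings contribute segments; chains traced to open or
  closed polylines.
* Zero-drift detection threshold: 0.05 cells per rotation over 10
  rotations (~2.6e-5 cells/ms at the working-point period).
* Transition curves: bisection in `nu` with majority vote over an odd
  number of frozen-heterogeneity seeds.

## Known limitations

* The rotor's slow orbit makes every drift measurement a multi-second
  simulation; the acceptance suite runs minutes, not seconds, and uses
  reduced boxes.
* Isotropic monodomain coupling only; no fibre orientation, no bidomain.
* The two-isoline tip definition is the only singularity detector
  (no phase/Hilbert methods).
* `alpha` near 0.7 prevents S1-S2 initiation (automaticity interferes),
  bounding the usable excitability range of the spiral protocols.
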