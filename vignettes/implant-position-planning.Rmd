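---
title: "Pre-planning the implant position for total knee arthroplasty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-planning the implant position for total knee arthroplasty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkaplan)
```

## The problem

Robotic-assisted total knee arthroplasty (TKA) can place the femoral and
tibial components within about a millimetre and a degree of a pre-operative
plan, but it does not answer *where* to place them. One proposed surgical
target is to restore the functional state of the *pre-diseased* knee — the
patient's knee before osteoarthritis — by choosing the component position
whose post-operative tibiofemoral kinematics and ligament strains best match
the pre-diseased curves during a standard movement.

`tkaplan` implements that planning loop end to end at desk scale:

1. a quasi-static rigid-body knee model simulating an *unloaded extension
   trial* (60° to 0° of flexion);
2. tibiofemoral kinematics expressed in the Grood–Suntay joint coordinate
   system (JCS) and ligament strains for eight bundles;
3. a mechanically aligned (MA) implantation baseline with a
   cruciate-retaining (CR) implant surrogate, and a 9-parameter placement
   vector `x` describing deviations from MA;
4. five surgical-target objective functions comparing implanted to
   pre-diseased curves, minimized by CMA-ES inside clinically motivated box
   bounds, with the clinically preferred near-optimum selected afterwards;
5. a synthetic-patient generator providing pre-diseased knees and
   hidden-truth benchmark scenarios, since no patient data ship with the
   package.

The numbered scripts under `analysis/` walk through the workflow: generate a
patient, simulate the pre-diseased trial, implant at MA, optimize the five
targets, and run the recovery benchmark.

## The knee model

Both bones carry a frame with x anterior, y proximal, z lateral
(right-knee convention; left knees are mirrored at input). The femur is
fixed; the tibia's pose relative to the femur is the six Grood–Suntay
coordinates: flexion (FE), external–internal rotation (EI), varus–valgus
(VV), and anterior (AP), lateral (LM) and proximal (PD) translations,
reported along the classic non-orthogonal JCS axis triad (flexion axis =
femoral z, EI axis = tibial y, VV = the floating axis). Internally the
rotation is the mobile z–x–y Euler sequence, which realises exactly that
axis assignment; the gimbal configuration VV = ±90° is rejected
explicitly. Signs follow the kinematic reporting convention: anterior,
lateral, proximal translations and external, varus rotations are positive.

### Ligaments

Eight bundles maintain stability: ACL, PCL, dMCL, sMCL, LCL, ALL, OPL and
PC. Each is a single straight line element (one bundle per named
structure, no wrapping) with the standard piecewise quadratic-toe/linear
spring in strain:

$$
f(\varepsilon) \;=\;
\begin{cases}
0 & \varepsilon \le 0\\[2pt]
k\,\varepsilon^2 / (4\,\varepsilon_l) & 0 < \varepsilon \le 2\varepsilon_l\\[2pt]
k\,(\varepsilon - \varepsilon_l) & \varepsilon > 2\varepsilon_l
\end{cases}
$$

with toe limit $\varepsilon_l = 0.03$ and stiffness $k$ in newtons per unit
strain. The force is continuous and C1 at the toe/linear transition and
slack bundles transmit no force. Slack lengths are calibrated from
per-bundle *reference strains* at a geometric full-extension resting pose —
a standard convention that makes the generator's reference strains the
primary tuning surface for the pre-diseased strain state.

### Contact

Articular and implant contact is a parametric surrogate rather than a mesh:
per-condyle femoral spheres articulating on per-compartment tibial height
profiles

$$ s(x,z) = y_0 + c_x x + a_x (x-x_c)^2 + a_z (z-z_c)^2 $$

evaluated in the tibial (insert) component frame, with an elastic law
$F = k_c\,d^{\,p}$ in the penetration depth $d$ (default $k_c = 300$
N/mm², $p = 2$). The force on the femur is the energy-consistent gradient
of the gap function, so a sloped or dished surface produces the tangential
force components that couple tibial slope to the AP equilibrium — the
coupling that makes tibial component flexion (slope) the most influential
placement parameter. On a flat surface the law reduces exactly to
stiffness × penetration^exponent along the surface normal. The native
lateral compartment is flatter and more posteriorly sloped than the medial
one, as in the native knee.

### Loading and the extension trial

The trial is unloaded: gravity is the only external load, acting on the
shank segment (default 4.5 kg, centre of mass 250 mm distal to the plateau
along the tibial axis) along the lab vertical, which at the seated posture
corresponds to the femoral −x direction. Flexion is a prescribed motion
driver; a quadriceps actuator is not modelled separately because, with
flexion prescribed in a quasi-static unloaded trial, the musculature only
carries the driven degree of freedom through the driver's reaction moment.

At each of `t = 60` uniformly spaced flexion samples (inclusive of both
endpoints, 60° … 0°), the five free coordinates (AP, LM, PD, EI, VV)
equilibrate quasi-statically: the solver minimizes the total potential
energy (gravity + ligament strain energy + contact energy) by damped Newton
iteration on its analytic gradient, with a finite-difference Hessian that is
reused across iterations and warm-started steps and refreshed when progress
stalls. Each step warm-starts from the previous solution; per-step failures
are flagged in the trace, never fatal.

**Residual contract.** A sample counts as dynamically consistent when the
Euclidean norm of the five generalized forces is below 5 N, with the two
moment residuals converted to force units through a 40 mm lever arm (the
norm and lever are package choices; the contract itself — 5 N — is the
standard the objective's penalty enforces). The solver's own tolerance is
1e-5 N, three orders tighter, so warm- and cold-started traces agree to
about 1e-6 on every coordinate and the objective is smooth enough for the
optimizer.

## Implantation and the placement vector

`ma_baseline()` implants the CR surrogate per mechanical alignment:
component axes aligned with the mechanical axes (neutral VV/EI, zero tibial
slope), 9 mm polyethylene insert, joint line restored by matching the
composite resection/implant thickness, and the ACL removed (it is resected
with a CR design; the other seven bundles are untouched). The femoral
component is a single-radius two-sphere surrogate; the insert is a
symmetric dished profile.

`implant_placement()` is the 9-vector `x` relative to MA: femoral AP/LM/PD
translations (mm) and FE/EI/VV rotations (deg), plus tibial FE/EI/VV
rotations. Tibial translations are structurally absent (they are fixed to
keep the problem well conditioned). The component sign convention follows
the planning table: posterior, medial, proximal, flexion, internal and
varus positive — deliberately distinct from the kinematic reporting signs,
with explicit converters at each interface. Bounds default to ±6 mm and
±6°, except femoral FE at ±3° (narrowed to avoid anterior notching of the
femoral cortex); no geometric notching computation is performed.
`apply_placement()` rigidly transforms the femoral component surfaces
(rotation order FE, then EI, then VV, intrinsic, about the femoral
component frame) and rotates the insert frame by the tibial parameters;
ligament attachments stay with their bones.

## Objectives, targets and the search

For a placement `x`, the objective is

$$
J(x) \;=\; \sum_{i=1}^{m} w_i \,\frac{1}{t}\sum_{\theta}
\bigl(y_{i,\theta}^{\mathrm{implanted}}(x) - y_{i,\theta}^{\mathrm{pre\text{-}diseased}}\bigr)^2
\;+\; P,
$$

where the $y_i$ are kinematic coordinates (mm, deg) and/or ligament strains
(unitless), averaged over the `t = 60` samples. The penalty $P = 10^3$ is
added once per triggered condition class per evaluation: always when any
sample violates the 5 N residual contract, and for the peak-capped target
additionally when any strain sample exceeds the peak of its pre-diseased
curve. The five targets:

| Target | Variables | Weights |
|---|---|---|
| ST1 | 5 kinematic coordinates | equal |
| ST2 | 7 ligament strains (post-resection set) | equal |
| ST3 | as ST2 | 8× on sMCL, dMCL, LCL |
| ST4 | as ST2 + per-ligament peak caps | equal |
| ST5 | all 12 | per-block, equal halves at MA |

ST5's weights rescale the kinematic and the strain block so that each
contributes exactly 0.5 of the penalty-free objective evaluated at the MA
baseline, making the MA objective exactly 1 by construction. The ACL never
enters a strain objective (it is resected), though pre-diseased ACL curves
are still reported. The 8× set in ST3 comprises the named collateral
structures only; the ALL, though lateral, is not a collateral in this
nomenclature and keeps unit weight. Strains enter the objective as unitless
strain, not percent — ST5's block normalization makes this choice
immaterial to the optimum, but it is fixed for reproducibility.

**Search.** CMA-ES (population 16, rank-one + rank-μ updates, cumulative
step-size adaptation) runs in coordinates normalized to [−1, 1] by the
bounds, with initial step 0.25 — a quarter of the bound half-width. Box
constraints are handled by clip-and-penalize: out-of-box proposals are
clipped for evaluation (so the candidate record only ever contains
in-bounds placements) and charged a quadratic distance penalty in the
optimizer's view. The search mean starts at MA, and `x = 0` is evaluated
first, so the best candidate can never be worse than MA. The default budget
is 2000 simulations; every evaluated candidate is retained as the solution
space.

**Clinical selection.** Among candidates within 5% of the best objective,
`select_clinical()` returns the one closest to MA in the root-sum-square of
bound-normalized parameters (making millimetres and degrees commensurate),
with deterministic ties broken by evaluation order. This encodes the
preference for solutions that stay surgically conventional when the
objective landscape is flat near its optimum — which it typically is, with
several near-equivalent placements.

## The synthetic patient

No clinical data ship with the package; `generate_knee()` supplies the
structure the analysis assumes. Attachment sites sit at anatomically
plausible locations (epicondyles, plateau rims, intercondylar points) with
the femoral points kept close to the flexion axis — the anatomical
isometry principle — so strain excursions over the arc stay physiological.
A seeded Gaussian jitter (0.8 mm s.d.) individualizes patients; the
envelope that generated pre-diseased strain curves stay within (−5%, 12%)
with positive peaks for at least six bundles is part of the generator's
contract and is enforced by tests. Default stiffnesses and reference
strains are frozen package constants from the nonlinear spring-ligament
literature, chosen once so the default patient's pre-diseased peaks land in
the low single percents and the MA baseline deviates from the pre-diseased
state by single-percent strains and about a millimetre / degree of
kinematics.

Two benchmark modes exist. *Hidden-truth* scenarios
(`make_hidden_truth()`) simulate the reference curves from the implanted
model at a known placement `x*`, so zero objective is attainable at `x*`
and optimizer acceptance is uncontaminated by model mismatch: the recovery
benchmark demands the best objective fall below 10⁻³ of the MA objective
within the 2000-evaluation budget, and it is this perfect-model setting in
which post-optimization kinematic RMSDs are required to beat MA on every
coordinate. The *realistic* mode uses the native pre-diseased trace as the
reference — there zero is unattainable because the implant geometry differs
from the native surfaces, exactly as in practice; the analysis scripts and
the acceptance script run this mode.

What the generator does *not* emulate: osteoarthritic remodeling and
osteophytes, menisci, cartilage thickness maps, patellofemoral mechanics,
multi-bundle ligaments and wrapping, and mesh-based contact. Passing tests
therefore demonstrate the planning machinery — simulation, objectives,
search, selection — not the anatomical fidelity of any individual knee.
One known qualitative divergence: on the default patient the largest MA
strain deviation is medial (dMCL) rather than lateral (LCL/ALL); the
surrogate's symmetric insert perturbs the medial compartment about as much
as the lateral one.

## Numerical choices

* **Sampling.** `t = 60` samples inclusive of both endpoints (step
  60/59°). The endpoint convention is exposed in `simulate_extension()`.
* **Solver.** Damped Newton with Armijo backtracking on the energy; near
  the double-precision energy floor a residual-decrease acceptance takes
  over (the energy scale is ~10³ N·mm, so decreases below ~10⁻¹⁰ N·mm are
  unmeasurable while the residual is still informative). Levenberg
  regularisation handles indefinite Hessians; maximum 200 iterations per
  step.
* **Degenerate inputs.** Gimbal poses are rejected in both compose and
  decompose; non-rigid transforms are rejected; out-of-working-range
  contact poses error in the user-facing contact evaluation and are
  range-flagged inside the solver.
* **Penalty granularity.** One penalty per condition class per evaluation
  (not per sample); a trace with many bad samples is penalized the same as
  one with a single bad sample, keeping the penalty a feasibility gate
  rather than a gradient signal.
* **Determinism.** Traces are bit-reproducible for identical inputs; the
  optimizer is reproducible given its seed; clinical selection breaks ties
  by evaluation order.
* **Problem sizes.** The test suite runs five hidden-truth recoveries at
  the full 2000-evaluation budget plus several smaller searches (300–600
  evaluations) for structural checks; the analysis scripts default to 1200
  evaluations per target (`TKAPLAN_BUDGET` overrides). These sizes give
  reproducible optima on the surrogate in seconds per run; the compiled
  core evaluates a full 60-sample trace in a few milliseconds.

## Limitations

The artifact is a planning-methodology testbed, not a validated
patient-specific model. Kinematic and strain magnitudes depend on surrogate
geometry and frozen mechanical defaults; absolute RMSDs are smaller than
those of CT-derived osteoarthritic patients, whose implant geometry departs
far more from their pre-diseased anatomy than our surrogate does from the
synthetic native knee. Results pertain to an unloaded extension trial only;
loaded activities, muscle recruitment, patellofemoral mechanics and
soft-tissue property changes with osteoarthritis progression are all out of
scope.
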