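---
title: "Localized adhesive dynamics of tumor cell–neutrophil capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized adhesive dynamics of tumor cell–neutrophil capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(adhesim)
```

`adhesim` simulates the adhesive capture of a melanoma tumor cell (TC) by
a substrate-adherent polymorphonuclear neutrophil (PMN) under near-wall
shear flow. This vignette is the package's account of the model: what is
being computed, which parameters matter, the numerical choices made where
the design was genuinely open, and what the simulator's verification does
and does not establish.

## The physical model

Three coupled pieces act on the tumor cell each timestep.

**Localized stochastic adhesion.** Both cell surfaces are triangulated;
adhesion molecules (ICAM-1 on the TC; the β2 integrins LFA-1 and Mac-1 on
the PMN) are distributed uniformly over the membrane, so a face of area
$A_L$ carries $n_L A_L$ molecules — deliberately *not* rounded, because
rounding would bias formation toward faces rounded up and break the
surface totals. All molecules on a face are treated as sitting at its
centroid. For every pair of faces (one per cell) whose centroid
separation $d$ lies inside the adhesive gate, bonds form and break with
the slip-bond rates

$$k_{on} = k_{on}^0 \, n_L A_L \, e^{-s_{ts}(d-\lambda)^2 / 2 k_B T},
\qquad
k_{off} = k_{off}^0 \, e^{(s - s_{ts})(d-\lambda)^2 / 2 k_B T},$$

converted to per-step event probabilities $P = 1 - e^{-k\,\Delta t}$
(memoryless: a bond gets a fresh, independent chance to break every
step; expected-lifetime effects emerge from the repeated trials). Formed
bonds persist across steps as Hookean springs $f = s(d-\lambda)$ acting
along the line joining the bonded centroids, and are re-measured at the
bodies' current poses before each breakage sweep.

Because membrane microvilli (about 0.5–1 μm) hold the surfaces much
farther apart than a 0.05 μm bond can reach, molecules are assumed to sit
at fully extended microvillus tips: the kinetic bond coordinate is
$d_{kin} = d - \varepsilon_{mv}$ with a standoff
$\varepsilon_{mv} = 1.2$ μm by default, and formation is gated to
$0 < d_{kin} < 2\lambda$ (beyond twice the equilibrium length the
exponential is negligible; the cutoff only trims useless work). The
standoff is physically crude — it is the simplest assumption that lets
bonding and repulsion coexist — and `kinetic_env(eps_mv = 0)` gives the
raw-distance fixture mode used in verification.

**Nonlinear-spring repulsion.** Every face pair closer than the critical
distance $\varepsilon = 1.2$ μm (the summed microvillus lengths of the
two cells) feels a lumped nonspecific repulsion
$F_{rep} = a d + b d^3$ standing in for microvillus pushing,
electrostatic repulsion and steric stabilization. With the reference
constants ($a < 0$) the polynomial has a zero at
$d^* = \sqrt{-a/b} \approx 0.43$ μm; read literally as "positive =
repulsive" it would *attract* inside $d^*$. The default `"clamped"`
convention therefore applies the push $\max(0, -(ad + bd^3))$ — purely
repulsive in contact, zero at and beyond $d^*$, continuous everywhere —
which matches the constants' stated calibration (maintaining roughly
0.3 μm of surface separation); `"signed"` mode preserves the printed
polynomial for fidelity experiments, discontinuity at $\varepsilon$ and
all.

**Rigid-body motion with a flow surrogate.** The TC is a rigid
uniform-density sphere ($m = \tfrac{4}{3}\pi r^3 \rho$,
$I = \tfrac{2}{5} m r^2$); the PMN is rigid and fixed to the substrate,
with zero net load by definition. Forces and torques from bonds,
repulsion and flow are summed componentwise at the centroid, exactly.
The hydrodynamic load is this package's one deliberate substitution: in
place of surface integrals of pressure and viscous stress over a CFD
solution, a linear shear profile $u_x(y) = G y$ drives wall-corrected
Stokes drag $F = 6\pi\mu r\, C_t(h/r)(u(h) - v)$ and a shear torque
$T = 8\pi\mu r^3 C_r(h/r)(\tfrac{1}{2}\omega_f - \omega)$, with
correction factors interpolated piecewise-linearly from a built-in table
over $h/r \in [1.05, 10]$ (computed from the classical
method-of-reflections expansions; constant beyond the table, $\ge 1$
everywhere). A force- and torque-free sphere therefore advects with the
fluid and spins at half its vorticity. Every output header carries this
surrogate disclaimer.

## Parameters

| Parameter | Value | Units | Origin |
|---|---|---|---|
| ICAM-1 density (TC) | $13\times10^{12}$ | m⁻² | reference set |
| LFA-1 / Mac-1 density (PMN) | $45 / 5 \times10^{12}$ | m⁻² | reference set |
| $k_{on}^0$ | 3000 | s⁻¹ per available molecule | reference set (see below) |
| $k_{off}^0$ (LFA-1 / Mac-1) | 0.3 / 0.29 | s⁻¹ | reference set |
| $s$, $s_{ts}$ | $2\times10^{-3}$, $1\times10^{-3}$ | N/m | reference set |
| $\lambda$ | 0.05 | μm | reference set |
| $a$, $b$ | $-110\times10^{-6}$, $600\times10^{6}$ | N/m, N/m³ | calibrated for ~0.3 μm separation |
| $\varepsilon$, $\varepsilon_{mv}$ | 1.2 | μm | microvillus lengths |
| $T$ | 310.15 | K | package default (body temperature) |
| $\Delta t$, steps | $10^{-3}$, 100 | s, – | steps from the reference scenario; $\Delta t$ a package default |
| $G$, $\mu$, $\rho_f$ | 100, $10^{-3}$, 1000 | s⁻¹, Pa·s, kg/m³ | package defaults (plasma-like) |
| TC radius; PMN cap | 4; base 5, height 5 | μm | package defaults (sizes are not part of the reference set) |

The printed unit of $k_{on}^0$ in its source ("1/Ms") is dimensionally
inconsistent with the rate expression producing s⁻¹; `adhesim` treats
$k_{on}^0 \cdot (\text{available molecule count})$ as a rate in s⁻¹,
i.e. 3000 per second per available partner molecule. The dissociation
constant $K_d = k_{off}/k_{on}$ can be shifted by editing $s$, $s_{ts}$
per bond type to model blood-chemistry changes; with $s = s_{ts}$ the
bond becomes ideal ($k_{off}$ distance-independent), which the tests
exercise.

## The molecule ledger and the fractional rule

Availability is book-kept per face *and* per species
(`molecule_ledger()`): a forming bond decrements both involved faces, a
breaking bond restores exactly what it consumed, so
$\text{available} + \text{consumed-by-live-bonds} = \text{initial}$
holds to $10^{-9}$ at every step (tested over 1000 form/break cycles).
Two-dimensional indexing is what prevents an ICAM-1 molecule engaged by
LFA-1 from being double-booked by Mac-1 in the same sweep.

A face holding $c = \lfloor c \rfloor + f$ molecules gets
$\lfloor c \rfloor$ uniform draws against $P$ plus one draw against
$f\cdot P$ — a face with 8.3 molecules draws nine numbers, the ninth
against $0.3P$ — so the expected count is exactly
$(\lfloor c \rfloor + f)P$. Three bookkeeping details were open and were
resolved as follows: a bond formed on the fractional draw consumes the
remaining fraction (`min(1, available)`), the consumed amount is stored
on the bond, and breakage returns it. This is the only combination that
keeps availability non-negative, conserves molecules exactly, and
preserves the $(\lfloor c\rfloor + f)P$ expectation simultaneously.

## The discretization correction factor

Local per-pair rates are rescaled so that their mean over the gated pairs
equals the single whole-contact-area rate
$k_{on}^{global} = \left[\sum n_L A_L\right] k_{on}^0
e^{-s_{ts}(d_{centroid}-\lambda)^2/2k_BT}$ with $d_{centroid}$ the
distance between the *cell* centroids. That identity is enforced to
$10^{-12}$ (relative) wherever it is computable. It is rarely computable
in whole-cell geometry: with cell centroids micrometres apart and
$\lambda = 0.05$ μm the exponent is of order $-10^7$ and the global rate
underflows to exactly zero in double precision. Rescaling by
$0/k_{on}^{avg}$ would erase the local rate structure, so the factor is
then forced to 1, a warning (or per-step counter) is raised, and the
identity remains meaningful on the planar verification fixture where the
plane centroids sit within the gate.

## Geometry and numerics

**Centroids on the surface.** All kinetics and repulsion act on face
*centroid* distances, but centroids of triangles inscribed in a sphere
sit a chord-sagitta inside it — ~0.07 μm at 1.5 μm elements, comparable
to the entire adhesive gate width. Meshes are therefore inflated so the
mean face-centroid radius equals the nominal cell radius
(`make_icosphere()`, and likewise the lateral surface of
`make_pmn_cap()`), placing the molecules on the membrane rather than
inside it. Total sphere area stays within 2% of $4\pi r^2$ from
subdivision 3 up (tested, with monotone error decrease).

**Pair search.** `gated_face_pairs()` prunes with exact bounding-sphere
bounds and bins faces into cells of side `cutoff`; its output contract is
*set equality with the brute-force all-pairs computation*, verified on
100 random configurations. Rows are ordered by
`(tc_face, pmn_face)` — the processing order of the stochastic sweep —
so runs are bit-identical for a fixed configuration and seed (the
processing order is not physically meaningful; fixing it is what makes
depletion reproducible).

**One step.** Geometry update → gated pairs → repulsion loads → breakage
sweep (existing bonds first) → formation sweep → bond loads → flow loads
→ aggregate → 6DOF step. Pairs whose pre-depletion formation probability
is below $10^{-14}$ are skipped without consuming random numbers;
availability only decreases within a sweep, so no feasible event is ever
dropped. One seeded generator drives the whole run; the seed is stamped
in every output header.

**Integrators.** At cell scale the inertial relaxation time
$m/6\pi\mu r$ is microseconds, far below any useful $\Delta t$, so the
default integrator is overdamped: velocities are set by instantaneous
balance of drag against bond + repulsion + external loads, then the pose
advances kinematically and the orientation quaternion is renormalized. A
semi-implicit Newtonian mode is retained for fidelity to the equations
of motion (momentum conservation under zero net force is tested to
machine precision). Overdamped stability near contact requires
$\Delta t$ below the ratio of drag coefficient to contact stiffness; the
approach experiments use $10^{-5}$ s for that reason.

## Verification scenarios

The planar fixture (`make_parallel_planes()`) — two co-registered rows of
faces, the full $n \times n$ pair-distance matrix, fixture mode
$\varepsilon_{mv} = 0$ — isolates the kinetics from meshes and flow
entirely. Forced $P = 1$ bonding on it checks availability limiting
(3.0 molecules against 2.0 yields exactly 2 bonds) and the
no-double-booking rule, against enumeration oracles on 100 randomized
instances.

`approach_experiment()` drives the TC onto the PMN apex with a constant
$10^{-11}$ N wall-ward load, adhesion off. With repulsion on, the
approach arrests: the minimum face separation stays at or above 0.3 μm,
settling just below $d^* \approx 0.43$ μm (the single-pair equilibrium
for that load is 0.37 μm by root-finding; distributing the push over many
faces can only raise it). With repulsion off the surfaces interpenetrate.
The package runs this with a subdivision-3 icosphere (1280 faces),
cap resolution 12, $\Delta t = 10^{-5}$ s, 2500 steps — sizes chosen so
the run settles to a steady state (residual velocity below $10^{-8}$ m/s)
in well under a minute.

## What the mesh-refinement experiment shows — a negative result

`mesh_independence_experiment()` meshes the identical two-cell geometry
at maximum element sizes 1.5 μm and 0.5 μm, holds the surfaces at the
repulsion-maintained 0.3 μm gap, and runs a single-instant formation
sweep per seed, drawing a uniformly random rigid orientation for each
mesh per seed so the Monte Carlo mean averages over the arbitrary
placement of elements on the same shape — the nuisance a
mesh-independence claim is about.

At the study conditions the mean bond counts do **not** agree: the
coarse mesh produces roughly a quarter of the fine mesh's bonds, a
difference of dozens of standard errors (the corresponding acceptance
test is deliberately left failing rather than weakened). The cause is
resolution, not statistics. Bonds can only form between face pairs whose
centroid separation falls in the offset gate
$(\varepsilon_{mv},\, \varepsilon_{mv} + 2\lambda)$ — a shell just
$2\lambda = 0.1$ μm thick — and the Bell exponential concentrates real
formation probability into a ±10 nm sub-shell. With 1.5 μm elements the
centroid spacing exceeds the shell thickness, so whether a coarse face
finds *any* partner inside the shell is a geometric lottery; faces that
miss contribute nothing while their molecules are stranded. The deficit
persists (at ~25%) even with the coupling interval shrunk until every
probability is small, i.e. it is not a saturation artifact, and the
correction factor cannot repair it: it normalizes the *mean* local rate,
not the pair-count-weighted sum — and degenerates to 1 at whole-cell
centroid separations anyway. The practical conclusion is a resolution
requirement: absolute bond counts from this class of localized model are
only meaningful when the surface elements resolve the $2\lambda$
reactive shell, far finer than the element sizes at which the cell-scale
comparison is usually run.

```{r mesh, eval = FALSE}
res <- mesh_independence_experiment(default_config(), seeds = 1:50)
res                  # per-resolution mean, SE, n
attr(res, "z")       # standardized coarse - fine difference
```

## What the synthetic geometry does and does not emulate

The PMN is a parametric spherical cap (default base 5 μm, height 5 μm —
a hemisphere whose solid centroid sits 1.9 μm above the substrate, near
the reference scenario's 2.5 μm), standing in for the flattened,
shear-rate-dependent shapes of real adherent neutrophils; the TC is a
perfect sphere. Real cells deform — contact flattening would widen the
adhesive zone and change both the repulsion calibration and the bond
census — and real adhesion molecules diffuse laterally and cluster,
whereas here they are frozen in the membrane at uniform density. Passing
tests therefore establish the internal consistency of the rigid-body,
fixed-density model, not fidelity to deformable-cell data. Selectin
kinetics and the endothelium are excluded by design; the substrate is a
geometric plane with no biochemistry.

## Known limitations

* The flow surrogate is one-way and sphere-specific: bond and repulsion
  forces do not perturb the fluid, and drag corrections assume an
  isolated sphere near a plane wall (the PMN's disturbance of the flow
  is ignored).
* The microvillus-tip standoff applies one $\varepsilon_{mv}$ to every
  face pair regardless of orientation.
* Absolute bond counts are mesh-resolution-dependent (above); trends
  and on/off contrasts are the robust outputs.
* `"signed"` repulsion reproduces the printed polynomial exactly but is
  attractive below $d^*$ and discontinuous at $\varepsilon$; it exists
  for fidelity experiments only.
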