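---
title: "Red cell deformability and capillary network hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Red cell deformability and capillary network hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rbcnet is a desk-scale computational laboratory for one question: how does a
loss of red blood cell (RBC) deformability — as in sickle cell disease,
malaria, diabetes, sepsis, or blood storage — change the hemodynamics of a
capillary network? The package runs paired experiments (normal cells versus
cells with a 10-fold higher membrane shear modulus, on identical geometry,
boundary conditions and cell insertion schedules) and reduces them to the
quantities microvascular physiology cares about: per-vessel hematocrit and
flow, partitioning of cells at bifurcations, lingering of cells at
bifurcation apices, flow resistance, and wall shear stress (WSS).

## The model

**Cells.** An RBC is a drop of hemoglobin solution (viscosity 0.006 Pa s)
enclosed by a hyperelastic membrane, suspended in plasma (0.0012 Pa s,
ratio 5). The resting shape is the Evans–Fung biconcave discocyte scaled to
an end-to-end distance of 7.8 um. In 3D the membrane resists shear and area
dilation through the Skalak strain energy

W = (G_S/4) (I1^2 + 2 I1 − 2 I2) + (C G_S/4) I2^2,

with invariants I1 = λ1² + λ2² − 2 and I2 = (λ1 λ2)² − 1, and bending
through the Helfrich energy E_b = 2 κ ∮ H² dA (zero spontaneous curvature).
Defaults: G_S = 5×10⁻⁶ N/m for normal cells and 10× that for "stiffer"
cells; C = 100 (the membrane is nearly area-incompressible; the source
studies do not state C, and any large value pins the area); κ = 2×10⁻¹⁹ J
(the conventional RBC value, likewise not stated in the sources). The 3D
machinery (`make_biconcave()`, `skalak_forces()`, `bending_forces()`) is
validated statically: forces are exact energy gradients (Skalak
analytically, Helfrich by complex-step differentiation of the discrete
cotangent-Laplacian energy), every evaluation is self-equilibrated, and the
sphere bending energy converges to 8πκ.

**The 2D reduction.** The flow core is two-dimensional: the full 3D
cell-resolved network problem needs ~10⁸ grid points and cluster hardware,
while every mechanism the analysis measures — disproportionate partitioning,
apex lingering, skewed hematocrit profiles, curvature-induced migration,
WSS localization — already exists in plane flow. Cells become closed
biconcave cross-section contours (`make_cell_contour_2d()`, 40 nodes by
default) carrying (i) a strain-hardening edge tension T(λ) =
G_S (λ − λ⁻³), an analog chosen to mimic Skalak stiffening (it is *not* the
3D law; the 3D law lives in the statically validated module), (ii) a
quadratic-curvature bending energy whose gradient is the periodic fourth
difference, and (iii) a weak area penalty. 2D "hematocrit" is an area
fraction and fluxes are per unit depth; a volumetric boundary flow rate in
nL/s is converted using the port diameter as the effective depth.

**Fluid and coupling.** Unsteady Stokes (no advection term) on a staggered
MAC grid, solved with an incremental pressure projection. The viscous term
is split: a constant-coefficient implicit operator at the hemoglobin
viscosity (cached sparse LU) plus an explicit "deficit" term
∇·((μ−μ_max)∇u); because the explicit coefficient never exceeds the
implicit one, the splitting is unconditionally stable, and the interior /
plasma viscosity contrast costs nothing per step. Walls are sharp-interface
ghost nodes: each exterior face near the wall carries the value that makes
the linear interpolant along its inward normal vanish exactly at the wall
foot. Membrane–fluid coupling uses the 4-point cosine kernel (exact
partition of unity, so interpolation reproduces constants and spreading
conserves total force, and the two operations are adjoint). Boundary
conditions: fixed pressures in port buffer cells (entered in mmHg), or a
parabolic Dirichlet inflow normalized to the exact flux (entered in nL/s).

**Seeding.** Cells are injected at the feeding vessel with randomized
lateral offsets and renewal-process timing calibrated so the time-averaged
inlet tube hematocrit converges to the target (30% by default). The
calibration solves the renewal equation with a refractory period (a new
cell must wait for the previous one to clear the insertion plane), so the
realized rate needs no empirical tuning. The seeding target is verified by
a kinematic transport measurement (`measure_inlet_hematocrit()`): scheduled
cells ride their lane speed and the cell-area fraction in a window at the
inlet cross-section is time-averaged. This isolates the calibration from
downstream cell–cell hydrodynamics; the same schedule drives the solver.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `Gs_N_m` | 5e-6 (×10 stiffer) | N/m | membrane shear modulus, the experiment's single knob |
| `C` | 100 | — | area-dilation ratio; large = near-incompressible |
| `kappa_J` | 2e-19 | J | bending modulus, conventional RBC value |
| `lambda_visc` | 5 | — | hemoglobin/plasma viscosity ratio |
| `hematocrit` | 0.30 | — | inlet tube hematocrit (area fraction in 2D) |
| `resolution` | 8–16 | points per cell diameter | 12+ recommended once cells flow |
| `window` | 0.1 s convention; configurable | ms | partitioning window |
| lingering `d_th`, `alpha`, `T_th` | feeder radius, 0.5, 5× tracer transit | | the detector's operational definition |

Diameters are kept in the capillary range 5.5–24 um; boundary pressure
defaults to 4.8 mmHg across the ports and boundary flow to ~1.25 nL/s
(interpreted as nL/s; the sources quote "1.2–1.3 nL" without a time unit).

## Statistics

Per vessel: tube hematocrit H(t) = (area of cells assigned to the gated
span)/(gated lumen area); the gate rule assigns a cell by centroid, one
local radius beyond the junction blend, and junction-region content is
excluded so nothing is counted twice. Q(t) is the mid-gate flux of the
velocity snapshots; resistance R = Δp/Q̄ from gate pressures; temporal CVs
H′, Q′; lateral 20-bin occupancy profiles with skewness (third standardized
moment) and the cell-free layer (mean wall-to-nearest-cell distance).
Paired deltas are percentages of the normal run; vessels whose normal flow
is below 10⁻³ of the network mean are flagged and suppressed. The spatial
CV of H across vessels uses the population standard deviation.

Per bifurcation: in consecutive windows, Q* integrates the daughter/mother
flow ratio and N* counts net gate crossings (a backward re-crossing
decrements). Windows with no mother crossing are invalid, never NaN.
Classification at the higher-flow daughter: regular if N*−Q* > 0.02,
reverse below −0.02, proportionate inside the band (the sources bucket
"~0" without a tolerance; 0.02 is this package's choice). f is the fraction
of windows below the N*=Q* diagonal; σ_N,Q = sqrt(Σ[(N*(t)−N̄*)² +
(Q*(t)−Q̄*)²]/M). For paired deltas the designated daughter is fixed by the
*normal* run's higher flow, so comparisons stay aligned if the split flips.
Δ_N−Q, Δf, ΔH^HF (absolute, not percentage) and Δγ follow directly.

Lingering is defined operationally — the sources describe it only
qualitatively: a cell lingers when its centroid stays within `d_th` (one
feeder radius) of the apex while moving slower than `alpha` (0.5) times its
own upstream mean speed (measured over the last 3 feeder radii of
approach), for at least `T_th` (5× the apex transit time of a centerline
tracer). All three thresholds are configurable and the detector is
sensitivity-tested (γ is non-increasing in `T_th`). γ divides distinct
lingering cells by distinct mother-gate passages.

WSS: from the time-averaged velocity, the axial traction t_s = μ ∂u_s/∂n
evaluated with the *plasma* viscosity (a plasma layer wets the wall) via a
one-sided quadratic fit through samples at 2h, 3h, 4h along the inward
normal — outside the IB kernel's smearing, where kernel smoothing of a
quadratic profile shifts all three samples by the same constant and leaves
the fitted slope unbiased. Reported in dyn/cm² (1 Pa = 10 dyn/cm²).
Δτ = (τ_stiffer − τ_normal)/τ_normal pointwise, floored at 1% of the
network median (absolute difference reported below the floor), with each
wall sample tagged apex-proximal (within 2 feeder radii), curved-outer-side
or other.

## Numerical choices and degenerate inputs

* Time step: the smaller of the tension scale μh/G_S and the bending scale
  μ ds³/(κπ³), times a 0.35 safety factor, capped by the advective CFL
  0.25 h/u_max measured on the developed cell-free flow (the flow is
  developed before any cell is inserted).
* The interpolated IB velocity is not exactly divergence-free, and
  under-resolved lubrication films during wall squeeze deflate a cell, so
  each contour's enclosed area is restored to its reference every step by
  an isotropic rescale about the centroid (a hard per-step constraint, the
  2D analog of the volume restoration used in cell-resolved 3D codes), on
  top of a weak area-penalty force; runs still abort with a diagnostic if
  any recorded area deviates beyond 5%.
* Membrane nodes approaching the ghost band receive a short-range wall
  repulsion along the inward normal; without it a cell squeezed against
  the wall samples the mirrored (sign-flipped) ghost velocities and its
  contour collapses.
* Walls are the zero level set of a smooth-minimum of per-segment capsule
  distances (blend width 1.5 um), extracted by contour tracing; port
  segments are extended beyond the domain so inlets/outlets are open
  cross-sections. A port placed in the domain interior would extend its
  branch's effective path — fixtures therefore keep outlet endpoints on
  the domain hull.
* Gate fluxes integrate the interpolated normal velocity across the lumen
  only (the ghost band's mirrored values would bias the integral low).
* Degenerate inputs error early and name the offender: zero-area membrane
  elements, non-manifold meshes, unknown fixtures, out-of-range diameters,
  infeasible winding (clearance check names the two segments), over- or
  under-constrained boundary conditions, geometrically unreachable
  hematocrit targets.

## What the synthetic generators emulate — and what they do not

`generate_network()` produces planar, tortuosity-controlled trees that
bifurcate, close into capillary loops and re-merge; diameters taper
Murray-like within 5.5–24 um. Real microvascular networks also have
out-of-plane crossings, multiple inlets, and empirically distributed branch
angles and lengths — none of which the sources quantify, so the generator's
defaults are conventional, not fitted. `synthesize_event_stream()` plants
exact routing probabilities and lingering episodes so every statistic can
be checked against truth without the solver; it has no hydrodynamics at
all. Passing those tests certifies the *bookkeeping*, not the physics; the
physics is certified separately against closed forms (Poiseuille velocity,
flux, resistance, wall shear; sphere and circle bending; partition-of-unity
and adjointness of the IB transfer) and by conservation laws on solver runs
(junction flux balance, per-cell area).

## Problem sizes

The shipped tests and the acceptance script run on one CPU at desk scale:
channels of 60–100 um at 8–32 points across, Y bifurcations at 12 points
per cell diameter, tens of milliseconds of model time with up to a few tens
of cells, and 0.5 s of kinematic seeding. These are the package's chosen
study sizes; the mechanisms of interest (disproportionate partitioning,
centerward migration ordering, suspension-elevated WSS) are resolved at
these sizes, while full network-scale replication of the source studies'
3D results is explicitly out of scope.

## Known limitations

* The 2D analog understates 3D effects with an essential circumferential
  component (fully developed cell-free-layer asymmetry, circumferential WSS
  gradients) and its contour tension law is an analog, not the Skalak law.
* Tube (not discharge) hematocrit is reported; the sources do not say which
  they use. Temporal and spatial CVs use the population convention.
* N* counts cell number flux, windows do not overlap, and γ counts distinct
  cells per junction passage — all flagged as open readings of the sources.
* The lingering thresholds are an operationalization; conclusions about γ
  should be checked across a threshold sweep (the API makes this a one-line
  change).
* Stiffer cells migrate no *faster* than normal ones only in weak
  confinement; in strong confinement (cell spanning most of the lumen)
  tumbling–wall interaction can dominate and invert the ordering in 2D.
  The migration property is therefore assessed in a 20 um channel.
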