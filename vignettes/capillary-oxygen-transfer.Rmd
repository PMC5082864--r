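---
title: "Modelling blood flow and oxygen transfer in feto-placental capillaries"
author: "capflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blood flow and oxygen transfer in feto-placental capillaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capflux)
```

## The physical problem

Oxygen reaches the fetus by diffusing from maternal blood in the
intervillous space, through the villous tissue, into the capillaries of
placental terminal villi, where fetal blood carries it away. Two features
make this problem distinctive. First, almost all of the oxygen in blood is
bound to hemoglobin rather than dissolved, so advection is far stronger
than the dissolved concentration alone suggests. Second, terminal-villus
capillaries often widen locally into *sinusoids* (localized dilations),
frequently together with a vasculo-syncytial membrane where the capillary
bulges against the villous surface; their functional role is debated.

`capflux` models a single capillary at three levels:

1. a **reduced-order model** of the total oxygen transfer rate `N` as a
   function of the pressure drop, built from boundary-layer and
   equilibrated transfer scalings, a diffusion-limited upper bound and a
   regression formula that bridges them;
2. an **axisymmetric finite-element model** of Stokes flow and
   hemoglobin-enhanced advection–diffusion in a capillary with a localized
   dilation, with oxygen supplied along the dilated wall section;
3. a **shape optimizer** that finds, at fixed pressure drop, the dilation
   profile maximizing `N`.

A companion module quantifies dilations in measured skeleton
radius-vs-arclength profiles, providing the geometric inputs to the
axisymmetric model.

## Hemoglobin-enhanced transport

Dissolved oxygen at concentration `c` obeys an advection–diffusion
balance; bound oxygen `c_h = c_max S(P_O2)` rides along with the flow but
does not diffuse (red cells diffuse far more slowly than plasma solutes).
With Henry's law `P_O2 = k_hn c / rho_bl` this folds into a single
equation,

$$\left(1 + \frac{c_{max} k_{hn}}{\rho_{bl}} S'(P_{O_2})\right)
  \mathbf{u}\cdot\nabla c = D \nabla^2 c .$$

Over the physiological fetal range (0–60 mmHg) the dissociation curve is
well approximated by a straight line through the origin, `S = K P_O2` with
`K = 0.019` per mmHg, making the bracket a constant *advection
enhancement* `B = 1 + c_max K k_hn / rho_bl ≈ 141`: each unit of dissolved
oxygen drags 140 bound units with it. The effective Péclet number is
therefore `Pe_eff = B u0 R0 / D`. Both `B` and `K` ship as defaults of
`transport_params()`; when the four constituents are supplied the
constructor checks them against `B` to machine precision.
`linearize_dissociation()` reproduces the constrained least-squares slope
from any sampled curve.

The nonlinear mode of `solve_oxygen()` keeps a user-supplied `S(P)`
(a documented Hill curve ships as an example — it is a generic sigmoid,
not a fitted fetal law) and iterates the local enhancement to a fixed
point with damped updates (initial damping 0.5, adaptively reduced if the
update stops contracting, relative-update tolerance 1e-8, cap 100
iterations). The advected total in the flux accounting is then
`c + c_max S(P(c))`, which the linearized model reduces to `B c`.

Default parameters (micrometre–second–Pascal–gram internal units):

| quantity | default | meaning |
|---|---|---|
| `D` | 1.7e3 um^2/s | oxygen diffusivity in plasma |
| `mu` | 1e-3 Pa s | plasma dynamic viscosity |
| `c_mat` | 0.07 mol/m^3 = 2.24 g/m^3 | maternal dissolved oxygen (≈52.5 mmHg) |
| `B` | 141 | advection enhancement |
| `K` | 0.019 /mmHg | linearized dissociation slope |

All converters live at the I/O boundary; `c_mat` may be given in mol/m^3
(molar mass 32 g/mol) or g/m^3. Transfer rates are reported in ug/s.

## The reduced-order model

For a capillary of length `L`, radius `R0` and vascular resistance `R`
(Poiseuille `R = 8 mu L / (pi R0^4)` if unmeasured), three regimes govern
`N(dP)`:

* **Boundary-layer (Graetz–Lévêque) regime.** At high `Pe_eff`, transfer
  happens in a thin wall layer and
  `N ≈ alpha c_mat (D^2 B dP L^2 / R)^{1/3}` with
  `alpha = (12 pi^2)^{1/3} / Gamma(4/3) ≈ 5.5`. This prefactor is exact
  for a circular tube with developed Poiseuille flow; applying it to
  irregular capillaries is an approximation valid for short vessels.
* **Equilibrated regime.** When oxygen reaches the centreline before the
  outlet (`Pe_eff ≪ L R0/(d+R0)^2`), the outflow saturates and
  `N ≈ c_mat B dP / R = c_mat B Q`.
* **Diffusion-limited bound.** With the capillary a perfect sink, tissue
  diffusion caps transfer at `N_max ≈ D A c_mat / (R0 ln(1 + d/R0))`,
  the exact solution for a concentric annulus of thickness `d`.

`regression_flow()` interpolates the two flow-limited regimes
(`N = K1 K2 dP / (K2 + K1 dP^{2/3})`), and
`villous_corrected_transfer()` folds in the villous tissue through
`N = N_flow / (1 + N_flow/N_max)`, which follows from setting the
capillary-surface concentration to the annulus solution
`c_inner = c_mat (1 − N/N_max)`. `classify_regime()` operationalizes the
strong inequalities of the regime map with a configurable separation
factor (default 10); borderline cases are reported as `"crossover"`
rather than guessed, because the regime map states inequalities, not
cutoffs. The regime inequality uses the longest inflow-to-outflow path
where available, while the transfer formulas use the total capillary
length — the total length is what reproduces the `L^2/R` scaling ratios
of the packaged morphometry table. Branched capillaries are treated as a
single equivalent tube throughout.

The packaged `table3_fixture()` carries the morphometry of three imaged
terminal-villus branches; its `N_max_numeric` column (computed by 3D
diffusion solves upstream of this package) is preferred over the annular
closed form in `predict_transfer()` when present, since the closed form
idealizes the geometry as concentric cylinders.

## The axisymmetric finite-element model

The dilated capillary is the solid of revolution of
`0 ≤ r ≤ R(z)`, `0 ≤ z ≤ L`, with `R(z)` a truncated Fourier series in
the dilation window and `R0` outside (see below). Blood flow is Stokes
flow driven by a fixed normal-stress difference `dP` between the inflow
and outflow planes (tangential velocity zero there, no slip at the wall,
symmetry at the axis). Because the inlet fixes the stress rather than a
velocity profile, the computed resistance includes entrance effects.
`calibrate_pressure()` supplies the `dP` that would give a 300 um/s
centreline speed in the undilated tube — the physiological speed scale
used throughout.

Oxygen enters only along the dilated wall section (`c = c_mat` there),
modelling a vasculo-syncytial membrane; inflowing blood is deoxygenated
(`c = 0`), and the undilated wall, outflow plane and axis carry zero
diffusive flux. An optional variant holds user-specified stretches of the
undilated wall at `c_mat` to approximate transfer upstream and downstream
of the dilation; it is labelled an approximation because it replaces the
exterior tissue problem by a boundary condition.

**Discretization.** Taylor–Hood elements (continuous P2 velocity, P1
pressure) on a structured triangulation, assembled in the r-weighted
axisymmetric weak form with the full strain-rate (stress-divergence)
operator, solved by sparse LU. The transport equation uses P1 elements on
the once-refined mesh (whose vertices are exactly the P2 nodes, so the
velocity transfers without projection) with streamline-upwind (SUPG)
stabilization active only where the element Péclet number exceeds one;
at `Pe_eff` of several hundred the unstabilized operator oscillates.
Radial grading clusters nodes at the wall so the first cell resolves a
boundary layer of thickness `R0 Pe^{-1/3}`. The axial grid always
contains the dilation-window endpoints, so the oxygenated wall section is
an exact union of element edges.

Numerical conventions worth knowing:

* On a straight tube the discrete solution contains the Poiseuille field
  exactly (quadratic velocity, linear pressure), so flow-recovery errors
  are round-off, not discretization.
* Boundary oxygen fluxes are computed by the consistent residual method
  (summing weak-form residuals over boundary nodes), not by
  differentiating the field at the wall; on coarse meshes the naive
  gradient is demonstrably worse. The reported `flux_balance_error`
  compares the advective outflow with the net diffusive influx and is
  about 0.1% at default resolution, tightening under refinement.
* The flow rate under exchange of the driving boundary agrees to machine
  precision (discrete reciprocity of the symmetric Stokes operator), the
  discrete analogue of Stokes-flow reversibility.
* The nondimensional concentration `chat = (c − c_in)/(c_mat − c_in)` is
  solved once in linear mode; `rescale_concentration()` maps it to any
  boundary values exactly without re-solving.
* Default problem sizes: 8–12 radial cells (about 1000–2500 quadratic
  elements, 5000–12 000 unknowns), chosen so that a full flow+transport
  solve takes a fraction of a second and successive refinements change
  `N` by well under 1%. The shipped tests exercise exactly these sizes.

## Dilation shapes

Inside the window of length `lam`, the wall is
`R(zeta)/R0 = a_0/2 + sum a_k cos(k pi zeta/lam) + sum b_k sin(k pi zeta/lam)`
subject to `R = R0` and `R' = 0` at both window ends — four linear
constraints that keep the wall continuous and smooth. `apply_constraints()`
eliminates the low-order coefficients (`a_0, a_1, b_1, b_2`, adjusted
when symmetry removes some) in terms of the free ones, so every
constructed shape satisfies the constraints to round-off; feasibility is
by construction, never by penalty.

Two symmetry conventions are exposed. The published zeroing rule (odd-`k`
coefficients set to zero) conflicts with Fourier parity for the sine
terms, whose even-`k` members are antisymmetric about the window
midpoint; the package therefore defaults to a strict-parity mode (even
cosines only, no sines), which is exactly mirror-symmetric, and offers
the stated rule as `"paper_odd_zero"` without guessing the original
intent. The one-degree-of-freedom family used for sweeps and as the
optimizer's first stage is the lowest symmetric member,
`R/R0 = 1 + (R_max/R0 − 1)(1 − cos(2 pi zeta/lam))/2`; each further
degree of freedom adds the next even cosine harmonic, so the families are
nested. An occlusion floor (default `0.2 R0`) guards against degenerate
channels; the dilation window is centred by default (configurable), as
the imaged geometry suggests but does not pin down.

## Shape optimization

`optimize_dilation()` maximizes `N` over the amplitude vector at fixed
`dP` using L-BFGS-B with central finite-difference gradients (step 1e-3
on the amplitude scale — the upstream workflow drove a black-box solver,
so derivative quality beyond FD is not on the table), from 10 seeded
random starts per stage (the protocol calls for at least ten);
`dof_continuation()` raises the degrees of freedom stage by stage,
seeding each stage with the previous optimum. Wall extrema are confined
to `[0.5, 2.5] R0` by an exact radial projection of the amplitude vector
(deviations from `R0` scale linearly, so the feasible scaling factor is
closed-form); a shipped test checks that widening the bounds changes the
optimal transfer by less than 1%. The optimum is re-evaluated at 1.5x
radial resolution and must agree within 1%; optimizer results are
cross-validated against the 1-DOF sweep (`sweep_1dof()`), the same check
the original protocol used.

At the study conditions (`Pe_eff ≈ 117` for the average-radius
configuration) the enhancement curve rises steeply to about 10% by
`R_max ≈ 1.5 R0`, flattens, peaks near `2.5 R0`, and falls beyond — the
interior optimum exists but is shallow, so the *transfer value* is
insensitive to the exact optimal radius. Two competing effects shape it:
widening lowers the resistance (raising `Q` and, with it, transfer) and
enlarges the oxygenated area, while slowing the local flow until the
dilated section saturates and, eventually, the slowdown wins. The
two-degree-of-freedom optimum trades a slightly smaller maximum radius
for a longer, flatter bump and a further gain in `N` — the optimized
dilation transfers about 15% more oxygen than the straight capillary at
the same pressure drop. A note on reported Péclet numbers: the package
always computes `Pe_eff = B u0 R0/D` from the calibrated centreline
speed; figures quoted elsewhere for this configuration (285, 475) cannot
be reconciled with that definition and are not used as targets.

## Measuring dilations in skeleton profiles

Skeletonization reduces a capillary to its centreline with a radius at
each point (distance to the nearest surface voxel). `measure_dilation()`
implements both endpoint definitions in use: *local minima* (the dilation
spans the two minima flanking the global maximum; `R0` is the branch
minimum) and *average crossing* (`R0` is the branch mean radius —
arclength-weighted trapezoidal mean, a choice this package fixes since
the weighting is not standardized — and the edges are where the profile
crosses it). Raw skeleton radii carry voxel-scale noise that makes
minima detection subjective, so endpoints are detected on a
moving-average smoothed profile (default window 3 um, recorded in the
output); amplitudes (`R0`, `R_max`) are read from the unsmoothed data.
Only the dominant dilation around the global maximum is measured.
`profile_to_shape()` closes the loop from measurement to model geometry.

## What the synthetic generator does and does not emulate

`make_bump_profile()` samples the one-degree-of-freedom bump and adds
seeded Gaussian radius noise (default scenarios use sigma = 0.1 um,
matching the voxel-quantization scatter visible in measured profiles;
the magnitude is configurable because no noise statistics are published).
It reproduces the *shape* and *noise level* of measured profiles, not
their asymmetries, multi-bump structure, centreline curvature or
correlated noise. Tests passing on these fixtures therefore validate the
estimator's behaviour under idealized conditions — symmetric single
dilations with independent noise — and say nothing about branched or
curved vessels, which the axisymmetric idealization excludes by design.

## Known limitations

* Blood is a Newtonian continuum with constant viscosity: no discrete red
  cells, no Fahraeus–Lindqvist radius dependence, no wall compliance.
* Tissue oxygen consumption by the syncytiotrophoblast is neglected.
* The axisymmetric model idealizes away centreline curvature and
  branching; the reduced-order model treats branched capillaries as one
  equivalent tube.
* The annular `N_max` underestimates bounds computed on real 3D
  geometries by roughly a factor of two (the packaged table carries
  both), so the closed form should be read as an order-of-magnitude
  estimate with the right ranking.
* The ref fetal dissociation polynomial is not redistributed; nonlinear
  runs require a user-supplied saturation law.
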