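---
title: "Methods: particle-laden bi-directional nasal airflow at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: particle-laden bi-directional nasal airflow at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasoaero)
```

## The problem

Targeting aerosolized drugs at the olfactory epithelium — the nose-to-brain
route — is hard: the olfactory region is a small, dorsal-posterior, poorly
ventilated patch of the nasal cavity. Bi-directional delivery (air pushed in
one nostril, around the nasopharyngeal U-turn behind a closed soft palate,
and out the other nostril) confines the aerosol to the nose, and
superimposed flow pulsation (a 45 Hz sinusoid, as produced by clinical
pulsatile nebulizers) is a candidate mechanism for reaching poorly
ventilated spaces. `nasoaero` implements the building blocks of a
computational assessment of this delivery mode — Lagrangian parcel
transport with Schiller–Naumann drag and two-way momentum coupling,
deposition-efficiency and dose-per-area accounting, a passive ventilation
tracer, and dynamic one-equation subgrid-scale (SGS) diagnostics — at desk
scale, on synthetic surrogate geometry.

## What is modelled, and what is not

A patient-specific CT airway and a pressure-coupled large-eddy momentum
solve are out of scope here. Instead:

* **Geometry** is generated: a straight duct and a curved bend for
  validation physics, and a parameterized *nasal surrogate* — two tall
  elliptic-slit channels joined by a 180° U-bend, with 45° nosepieces, a
  valve-like constriction, seeded mucosal wall roughness, and labelled
  dorsal olfactory wall patches.
* **Flow** is prescribed, not solved: a mass-conserving quasi-one-dimensional
  laminar field along the sweep centerline (elliptic-duct parabolic profile,
  stream-tube radial correction in converging sections), optionally scaled
  in time by the inlet waveform `U(t) = U0 (1 + sin(2 pi omega t))`
  (quasi-steady pulsation).
* **Particles** are Lagrangian parcels with statistical weights, advanced by
  the exact solution of `du/dt = (u_s - u)/tau_p + g` over each sub-step
  with the gas velocity frozen; `tau_p = rho_p d_p^2 / (18 mu) / f_d` with
  the Schiller–Naumann drag factor. Parcels stick to the wall on first
  contact (segment–triangle test against the surface mesh) and escape
  through the outlet cap.

Because the pulsatile flow is quasi-steady — the instantaneous field is the
base field times a scalar — the genuinely unsteady mechanisms by which
pulsation restructures nasal flow (oscillatory boundary layers, altered
impingement after the nasal valve; the Womersley number at 45 Hz in a 5 mm
duct is ≈ 22) are *not* represented. A 1 µm tracer's pulsatile trajectory is
then essentially a time-reparameterization of its steady trajectory, so
steady and pulsatile deposition come out nearly equal here, whereas resolved
simulations report a reduction under pulsation. The package's directional
test therefore checks that pulsation does not *increase* deposition beyond
parcel sampling error, and the steady/pulsatile endpoint comparison should
be read with this approximation in mind.

## The synthetic surrogate and its calibration

Real nasal passages are narrow, tall slits with an enormous
surface-to-volume ratio. The surrogate reproduces this with elliptic
cross-sections of half-height 30 mm and half-width 2 mm. Defaults were
calibrated once, at design time, against the reported area anatomy:

* olfactory patch areas ≈ 330 mm² (right) and 337 mm² (left),
* total cavity wall area ≈ 64× the combined olfactory area,
* enclosed volume ≈ 69 mL, so that at 4 L/min the mean residence time
  (≈ 1 s) fits inside the 1.98 s simulated delivery window.

The olfactory bands are dorsal angular windows (±1 rad about the top of the
slit) over exact streamwise windows; centerline stations are inserted at the
window edges so the patch areas vary continuously with the window length
(not in triangle-row quanta). The seeded wall roughness (±1 % radial, two
azimuthal/streamwise modes) makes distinct seeds produce distinct meshes
while changing patch areas by well under 1 %.

What passing tests on this geometry do *not* show: patient-specific
deposition fractions. The reported patient values (e.g. total DE 50.9 %
steady vs 34.4 % pulsatile) are bound to an individual CT geometry and a
20-million-cell resolved simulation; on the surrogate with prescribed
laminar flow, total DE for 1 µm parcels is of order 10 % (dominated by the
inlet nosepiece and vestibule) and olfactory DE is essentially zero — the
correct *direction* (olfactory ≪ total) at desk scale.

## Numerical choices

* **Grids.** Isotropic voxel grids; the implicit filter width is
  `(V_cell)^{1/3} = dx` exactly. Inside/outside is decided by ray parity per
  grid column with deterministic jitter against grazing rays; watertight
  input is validated (every edge shared by exactly two triangles). Cell-center
  counting makes the recovered volume fluctuate within a few percent of the
  analytic volume at `dx = r/8` (a lattice point-count effect, not a bias).
* **Time stepping.** The transport loop uses the Courant bound
  `dt = C_max dx / max|u|` (plus 1/40 of the pulsation period in pulsatile
  mode). The classical additional cap `dt <= tau_p/5` is implemented in
  `adaptive_dt()` but not applied by default: the analytic sub-step is exact
  for any `dt` at frozen gas velocity, and for 1 µm parcels
  (`tau ≈ 3.1e-6 s`) the cap would demand ~3×10⁶ steps for a 1.98 s run
  with no accuracy benefit.
* **Drag factor.** The three-branch Schiller–Naumann factor
  `f_d = 1`, `1 + 0.15 Re^0.678`, `0.44 Re/24` — the reading that is
  continuous at `Re = 1000` within 7 % and reduces to Stokes drag, and is
  consistent with `tau_p = tau_St/f_d`.
* **Two-way coupling.** The drag reaction is scattered to the eight
  surrounding cells with trilinear weights as a force density, satisfying
  `sum_cells S V_cell = -sum_p w_p F_D` to rounding. In prescribed-flow mode
  the source is computed and reported each step (optionally applied as a
  perturbation `u += S dt/rho`); full feedback would require the momentum
  solver that is out of scope. The reference injection (2.5 mg over 0.5 s at
  4 L/min) has particle volume fraction 7.5×10⁻⁵, above the 10⁻⁶ dilute
  threshold, so two-way accounting is physically warranted.
* **SGS diagnostics.** The localized dynamic one-equation closure is
  implemented as testable field operators: top-hat 3³ test filter (one-sided
  at boundaries), Germano resolved stress `L_ij`, the two-filter-level
  scalar `M`, and dynamic `Ck`, `Ce` via 3³-stencil volume averages. As
  printed, the `M` quantity carries no free tensor indices; both contraction
  conventions against `L_ij` (trace, or through the unit strain direction)
  are exposed, with the strain convention as default. Coefficients are
  clipped (`Ck in [0, 0.5]`, `Ce in [0.5, 5]`) and fall back to the
  standard constants `Ck = 0.094`, `Ce = 1.048` where the contractions
  degenerate (e.g. strain-free flow); unclipped dynamic coefficients are
  numerically unstable and backscatter is excluded for robustness. `k_SGS`
  transport uses first-order upwind advection, central conservative
  diffusion, and explicit stepping under advective/diffusive stability
  bounds, clipped at zero.
* **Ventilation tracer.** `C` (drug-laden-air fraction, 1 at the inlet) is
  advected by donor-cell upwind fluxes and diffused with total diffusivity
  `nu/Sc + nu_sgs/Sc_sgs` inside the divergence (conservative for varying
  eddy viscosity), with zero-flux wall faces and a clamp to `[0, 1]`.
  `Sc = Sc_sgs = 0.7` by default (air-like tracer; both are configurable as
  no reference values are stated).
* **Air properties.** `nu = 1.5e-5 m²/s`, `rho = 1.2 kg/m³`,
  `mu = 1.8e-5 Pa s` (room-temperature air; configurable). Particle density
  defaults to water (1000 kg/m³), matching aqueous drug formulations.
* **Gravity.** Configurable; default `-z`, with the surrogate's dorsal
  olfactory pockets at `+z` (head orientation is otherwise unspecified).

## Problem sizes used by the tests and the acceptance script

Desk-scale statistics replace the production configuration of 4×10⁶ parcels
on 2×10⁷ cells: the surrogate experiment runs 2000 parcels on a ~6.3M-cell
grid (0.47 mm cells, ~0.67M fluid cells), the bend sweep 1500 parcels per
diameter, and property tests use a reduced-scale surrogate with identical
topology. Parcel weights always rescale to the full 2.5 mg injected mass,
so dose-per-area magnitudes remain physical. Statistical error on a DE of a
few percent with 2000 parcels is a few tenths of a percentage point; the
monotonicity and conservation checks are insensitive to this level.

## Known limitations

* Prescribed quasi-1D flow: no secondary flows in bends, no turbulent
  dispersion, no unsteady restructuring under pulsation (see above). Small
  wall-normal velocity errors near strongly morphing sections deposit a few
  percent of tracer parcels that a resolved flow would keep airborne.
* Particle equations carry drag and gravity only — no Brownian diffusion
  term, so the diffusional contribution to olfactory deposition of ~1 µm
  particles is not represented.
* The scalar, k-equation and quality-index operators are diagnostics on
  prescribed or supplied fields; they do not feed back into a momentum
  solve.
* `k_res` for the resolution-quality index `M = k_res/(k_res + k_sgs)` is
  computed from velocity snapshots over a caller-chosen time window, since
  no averaging window is standardized.
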