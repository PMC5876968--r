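---
title: "Modelling catheter-generated perfluorocarbon aerosols: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling catheter-generated perfluorocarbon aerosols: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcaerosol)
```

## The problem

Respiratory distress syndrome in preterm infants is treated with exogenous
surfactant, and perfluorocarbon (PFC) liquids — here perfluorodecalin (PFD,
density 1.95 g/mL) and FC75 (1.78 g/mL) — are candidate carrier aerosols
for less invasive administration. An intracorporeal inhalation catheter
atomizes the liquid with compressed air at 4–5 bar: a central lumen feeds
the liquid, an outer ring of lumens feeds high-velocity air, and the
resulting spray is characterized downstream by a time-of-flight particle
sizer over its 0.5–20 µm measuring range.

`pfcaerosol` is a desk-scale model of this system. It transports the
droplet population measured at the injection plane through a calibrated
surrogate jet with a Lagrangian parcel solver, applies secondary breakup,
and computes the aerosol statistics by which such sprays are judged:
the mass median aerodynamic diameter (MMAD), the geometric standard
deviation (GSD, heterodisperse above 1.25), the cumulative mass
distribution over droplet size, and the aerosolization rate. A
Richardson-extrapolation / grid-convergence-index (GCI) toolkit supports
solution verification of mesh studies.

## The surrogate carrier field

The catheter's air jet would normally be obtained from a compressible RANS
solution; that field is not reproducible at desk scale, and the droplet
phase only needs a plausible calibrated carrier. The package therefore
uses the classical self-similar turbulent round jet:

* a potential core of constant centerline velocity up to `x_core`
  (default 4 mm), then `u_c(x) ∝ 1/x`;
* a Gaussian radial profile with half-width
  `r_half(x) = r_0 + 0.094 x` (the standard round-jet spreading rate);
* turbulent kinetic energy from an intensity profile,
  `k = 3/2 (I u)^2` with `I = 0.1` by default;
* dissipation closed by `l_eps = 0.07 L` (ring width `L`, default 0.1 mm)
  and `epsilon = C_mu^{1/2} k^{3/2} / l_eps`, `C_mu = 0.09`.

The one empirical anchor is the measured centerline velocity at the
droplet-injection plane, 2 mm downstream of the tip: 247 m/s at 4 bar and
293 m/s at 5 bar. The core velocity is chosen so the sampled field
reproduces these values exactly:

```{r}
sample_flow(2e-3, 0, jet_flow_config(4))$axial_velocity
sample_flow(2e-3, 0, jet_flow_config(5))$axial_velocity
```

Compressibility is not modelled (the real tip flow is transonic; the
surrogate only carries droplets), the mean radial velocity is taken as
zero, and the lumen geometry — never published — enters only through
configurable lengths (`annulus_width_L`, `jet_half_width_0`,
`injection_line_length`). Air properties default to 20 °C values.

## Lagrangian droplet transport

Parcels — groups of identical droplets — obey Newton's second law with
only the Schiller–Naumann drag force,
`F_D = 1/2 C_D rho_g A_p |v_rel| v_rel`,
`C_D = 24/Re (1 + 0.15 Re^{0.687})` for `Re ≤ 1000` and 0.44 beyond.
Gravity, virtual mass, Basset history and pressure-gradient forces are
neglected: the liquid is ~1600 times denser than the gas, so drag
dominates. Because micron droplets have relaxation times
`tau_p = rho_l D^2 / (18 mu_g)` down to ~1e-7 s, far below the 1e-4 s
time-step, the drag update is a semi-implicit exponential integrator —
exact for linear drag over a frozen substep — and each global step is
divided into substeps (up to 20) sized so a fast parcel moves no more
than ~1.25 mm per substep through the spatially varying field.

Turbulent dispersion uses the eddy-interaction (discrete random walk)
model: each parcel sees a fluctuation drawn per component from
`N(0, 2k/3)` for the minimum of the eddy lifetime `l_eps/|u'|` and the
linearized crossing time, then a new eddy is sampled. Near the injector
the eddy times (~3e-7 s) are shorter than a substep, so eddies there
decorrelate effectively once per substep; dispersion at that scale is
therefore resolution-limited, a known property of this class of model at
coarse steps, and one reason outlet statistics — not near-field
trajectories — are the quantities this package reports.

Coupling is one-way: a prescribed field cannot receive momentum sources,
so instead of the under-relaxed two-way exchange a full CFD run would use,
the solver accumulates the momentum handed to the gas each step as a
diagnostic (`step_log$momentum_exchange_Ns`), making the size of the
approximation visible. Droplet–droplet collision/coalescence and
evaporation/condensation are excluded from the model's scope entirely.

## Secondary breakup (TAB)

Droplet distortion follows the Taylor-analogy spring–mass system with the
canonical constants `C_F = 1/3, C_k = 8, C_d = 5, C_b = 0.5`: aerodynamic
pressure (∝ Weber number `We = rho_g u_rel^2 D / sigma`) forces the
distortion `y`, surface tension restores it, liquid viscosity damps it,
and `y > 1` triggers breakup. The oscillator is advanced with its exact
analytic solution per substep (trigonometric, hyperbolic or critical
branch as the damping dictates; the overdamped branch is written in
root form so that stiff sub-micron droplets cannot overflow). On breakup
the parent is replaced by 10 equal-mass children whose Sauter mean
follows the TAB energy balance (`K = 10/3`) and whose diameters are drawn
from a Rosin–Rammler law (spread `q = 3.5`, configurable) truncated
strictly below the parent diameter — so breakup conserves liquid mass to
machine precision by construction.

Surface tension and viscosity of PFD and FC75 are *externally sourced
handbook values* (0.019/0.015 N/m, 5.1e-3/1.4e-3 Pa·s), not measured
inputs; they are configurable through `compound_properties()`. At the
operating conditions the droplet Weber numbers stay far below the `We <
100` validity bound of TAB (trial runs peak near 30), and breakup events
are correspondingly rare.

## Injection

The ten-injector tables packaged under `inst/extdata/` give the measured
geometric diameter and liquid mass flow per injector for the four
scenarios (PFD/FC75 × 4/5 bar); totals are always recomputed from the
columns. Parcels are allocated to injectors proportionally to mass flow
with largest-remainder rounding (each active injector emits at least one
parcel), the per-parcel droplet count is set so the emitted mass equals
`total_mass_flow × dt` exactly each step, parcels start on the injection
plane uniformly along a radial line, and their initial velocity is the
local gas velocity. `rebin_aps_to_injections()` rebuilds such a table
from any 52-interval histogram by mass-conserving rebinning in
log-diameter, with the representative diameter of each injection taken as
the mass-weighted geometric mean.

## Aerosol statistics

All quantile statistics (MMAD, GSD) interpolate log-linearly in diameter
within the crossing bin, the standard instrument convention; GSD uses the
quantile ratio `sqrt(d_{84.1}/d_{15.9})`, which is robust for binned data
and agrees with `exp(sd(ln d))` for lognormal input (tested). A
distribution whose mass sits in a single bin is treated as a point mass
at the bin's geometric midpoint, so monodisperse aerosols report GSD = 1
rather than an artefactual within-bin spread. Aerodynamic and geometric
diameters convert by `Dg = Da sqrt(rho_0/rho)`.

## Synthetic data

`generate_aps_sample()` emulates an instrument sample from a lognormal
aerosol, the family whose sufficient parameters (mass median, GSD) are
exactly the reported statistics. Draws are *mass-weighted* (each draw is
an equal mass share), classified into the instrument's four events
(below range / in range / coincidence / above range), and binned into 52
logarithmic intervals over 0.5–20 µm; true instrument bin edges are
proprietary, so log-uniform edges are used. Per-bin particle counts are
scaled from bin mass by the midpoint diameter cubed, hence real-valued.

One consequence the tests make explicit: the instrument truncates at
20 µm, so for a wide aerosol (e.g. mass median 7.2 µm, GSD 1.9, where
5.6% of mass lies beyond range) the histogram's recovered MMAD is the
*range-truncated* median (6.88 µm for that case), not the generating
median. Generator tests therefore compare against closed-form
truncated-lognormal quantiles; parameter-recovery claims for the metrics
themselves are checked on untruncated samples. Passing tests show the
statistics pipeline is correct — they do not show that a real catheter
aerosol is lognormal, nor do they reproduce instrument optics,
concentration effects or sampling bias.

## Solution verification (Richardson / GCI)

From three mesh solutions `v1, v2, v3` (fine to coarse, refinement ratio
`r`): observed order `p = ln((v3−v2)/(v2−v1))/ln r`, extrapolated value
`v1 + (v1−v2)/(r^p−1)`, and `GCI = Fs |Δv|/|v_ref|/(r^p−1) × 100` with
`Fs = 1.25`. Two conventions matter and are configurable:

* `r` defaults to 2, matching the order formula's `ln 2` even though the
  cell counts of a typical study imply a slightly different per-dimension
  ratio;
* each GCI normalizes by the **coarser** solution of its pair. This
  choice reproduces reference tabulations exactly (e.g. GCI23 = 3.65%
  from 9.58/9.41/8.92 m/s, where fine-normalization gives 3.46%), and it
  implies an exact identity the tests assert: for error-free `p`-th-order
  data the asymptotic ratio `GCI23/(r^p GCI12)` equals `v2/v3`
  identically — near 1 only when discretization errors are small, which
  is precisely what the asymptotic-range check is for.

## Numerical choices and degenerate inputs

* Time-step 1e-4 s, 500 parcels/step, 0.06 s release with a 0.01 s
  analysis window are the study defaults in `run_config()`; scaled runs
  in the tests use 0.02 s, which is ample since jet transit takes ~2 ms.
* Emission is exactly mass-balanced per step regardless of parcel count;
  parcel count only changes statistical noise. The mass-balance report
  gives both the window-averaged outlet/inlet ratio and the rms per-step
  imbalance (the quantity that shrinks visibly as parcels/step grows
  100 → 500 → 1000).
* Parcels leaving upstream (`x < 0`, rare) are removed and their mass
  reported separately; there is no radial boundary.
* `observed_order()` refuses converged pairs and oscillatory convergence
  with named errors; zero-mass distributions, non-normalized cumulative
  curves, and out-of-domain flow samples are rejected rather than guessed
  at.
* All stochastic stages (eddies, breakup child sizing, synthetic
  generators) are pure functions of the supplied seed; with turbulence
  disabled the transport is seed-independent and bit-reproducible.

## Known limitations

The carrier field is a calibrated correlation, not a flow solution: peak
tip velocities, the near-field shear layer and compressibility effects
are outside its scope, and simulated/measured cumulative-mass differences
cannot be attributed between transport error and carrier-field error.
One-way coupling overestimates the gas's ability to carry dense sprays at
the near-field volume loadings. Coalescence — which the measured-vs-
modelled comparisons themselves suggest matters — is excluded. These are
scope boundaries of the desk-scale model, not tunable deficiencies.
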