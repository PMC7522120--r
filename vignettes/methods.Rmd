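---
title: "Methods: from binding kinetics to absorbed dose for intraperitoneal 211At antibody therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from binding kinetics to absorbed dose for intraperitoneal 211At antibody therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`atdosim` models the chain of physical and biological steps that determines
the absorbed dose delivered to single tumor cells and microscopic tumor
clusters by an astatine-211-labeled antibody administered into the
peritoneal cavity. This vignette documents the models, the default
parameter values and why they were chosen, the numerical methods, the key
design decisions, and the limitations.

## 1. Nuclear and track physics (`decay_scheme`, `stopping_power_water`)

211At is treated as a pure alpha emitter with half-life 7.21 h and two
branches, each producing exactly one alpha particle: 41.8% at 5.87 MeV
(direct decay) and 58.2% at 7.45 MeV (via the short-lived 211Po daughter,
whose half-life of ~0.5 s is collapsed into the parent decay). Photons
(abundance 0.43 per decay in the 77–93 keV window, retained for counting
arithmetic) and electrons are ignored dosimetrically: at cellular distances
the alpha contribution dominates. The scheme ships as a JSON resource in
`inst/extdata` so the nuclear data are inspectable outside R.

Alpha transport uses the continuous-slowing-down approximation (CSDA) on
straight tracks in unit-density water. The stopping power is a two-regime
power law, `S(E) = k E^-0.671` above 1 MeV rolling over to `k E^0.3`
below, with `k = 0.2627491` calibrated so the analytic range integral
gives R(5.87 MeV) = 47.0 um; the implied R(7.45 MeV) = 68.5 um falls
within a few percent of published alpha-in-water ranges. The Bragg peak is
represented implicitly by the steep rise of `S` at low energy. Straggling,
delta-ray escape, and nuclear recoil are not modeled. Energy deposited in
a target along a track segment is computed by residual-energy
differencing, which makes the Monte Carlo exact given the range table.

## 2. Binding kinetics (`binding_model`, `simulate_assay`)

Antibody–antigen binding on suspended cells follows a multi-component
reversible mass-action model with a shared free-ligand pool:

- dB_i/dt = k_on,i L (S_i − B_i) − k_off,i B_i (bound per cell),
- dL/dt = −Σ dB_i/dt · cells/V/N_A (molar depletion).

The default `farletuzumab_model()` has two classes of 300,000 sites each:
k_on 5.06e5 M⁻¹s⁻¹ / k_off 5.61e-3 s⁻¹ (Kd 11.1 nM) and 2.25e5 / 5.02e-4
(Kd 2.23 nM). Internalization is not modeled. Protocols are event
schedules (wash, dilute, measure); a wash instantaneously removes a
fraction of the free ligand, after which bound antibody dissociates at
k_off. The canonical `cell_binding_protocol()` (2e6 cells, 2 mL, 0.4
ug/mL) models the bench procedure as two wash cycles of 2 min handling
each, so counting happens 4 min after the incubation ends. **Design
decision:** the headline "bound per cell after 1 h" quantity is read at
this post-wash measurement point, not at the instant of the wash — the
fast-dissociating component (half-time ~2 min) loses a substantial part of
its occupancy during real washing, and simulated counts are meant to be
comparable with counted pellets. Mass balance (free + bound + removed) is
checked to 1e-6 on every run.

The algebraic depletion-corrected equilibrium (`equilibrium_binding`) is
solved independently by `uniroot` and serves as the ODE oracle in tests.

Radiolabeling arithmetic: a specific activity SA implies a labeled
fraction `(SA/λ)/(N_A/M)`; the default 2.3 GBq/mg with M = 150 kDa gives
one labeled antibody in 46.6. The Lindmo immunoreactive-fraction assay is
forward-simulated (`simulate_irf_assay`) including the wash-time
dissociation, which is why an intrinsically fully reactive two-component
preparation still shows an apparent IRF near 0.5.

Fitting (`fit_binding_model`) minimizes squared log-residuals
(multiplicative counting error) over log10-scaled parameters with seeded
multi-start (Nelder–Mead then BFGS). **Limitation:** a single
low-concentration time course identifies the product k_on × sites much
better than either factor (occupancy far from saturation); fits are
validated on their predicted curves, and saturation-series data are needed
for full parameter identifiability.

## 3. Intraperitoneal pharmacokinetics (`compartment_pk`)

The cavity activity concentration is mono-exponential,
C(t) = C0 · exp(−(λ_bio + λ_phys)t). The mouse scenario administers 700
kBq in 0.7 mL (1000 kBq/mL) with λ_bio calibrated to 4·λ_phys; the patient
scenario 300 MBq in 1.5 L (200 kBq/mL) with λ_bio = 0. The calibration
makes the cumulated decay concentration C0/λ_eff identical in the two
scenarios (7.49e9 decays/mL), so the mouse experiment is a 5×-concentration
surrogate for the clinical treatment; `translation_factor()` returns that
ratio. Only cumulated decays feed the dosimetry, so the mono-exponential
simplification is exact for the quantities consumed downstream.

## 4. Antibody penetration into microtumors (`simulate_penetration`)

Spherical microtumors are modeled as a porous medium: free antibody
diffuses in the accessible interstitial fraction (ε = 0.2 by default,
diffusivity 10 um²/s) and binds reversibly to immobile antigen. With the
default tissue cell density of 1e-3 cells/um³ (tightly packed ~12 um
cells) and 600,000 sites/cell, the antigen concentration is ~1 uM of
tissue — three orders of magnitude above the nM-range antibody
concentration. This is the binding-site barrier: effective diffusivity is
retarded by a factor ~(1 + Σc_sites,i/(ε Kd_i)) ≈ 10³, so on therapy
timescales the bound antibody concentrates in the outer cell layers while
tumors a few cell diameters across equilibrate fully (total uptake then
scales with cell number, the regime probed by `uptake_regression`).

Numerics: conservative finite-volume discretization of the spherical
Laplacian on a ≤2 um grid, method of lines with `deSolve::lsoda` and a
banded Jacobian; the bath is either a prescribed decaying boundary value
or a finite closed volume (used for mass-conservation verification, which
holds to ~1e-15 relative). The solver was additionally verified against an
independent explicit-Euler integration.

The time-resolved field is converted to a radial cumulated-decay density
by weighting bound plus interstitial free antibody with the labeled
fraction decaying physically, f0·λ_p·exp(−λ_p t), trapezoid in time plus
an analytic exponential tail.

## 5. Monte-Carlo dosimetry (`dose_bath_to_nucleus`, `dose_profile_sphere`)

All estimators share one track engine: decay positions sampled from the
source distribution, isotropic emission, branch-sampled energy, and
residual-energy differencing at target-boundary crossings (geometry is
concentric spheres, so positions can be placed on an axis without loss of
generality). Every estimator takes an explicit seed, is bit-reproducible,
and restores the caller's RNG state.

- *Bath estimator*: a 7.5 um cell with a concentric 5 um nucleus in an
  effectively infinite uniform bath (sampling shell extends one maximum
  alpha range + 5 um margin). The homogeneous-medium limit has the closed
  form D = C̃·Ē/ρ (`equilibrium_dose`), used as a 3-standard-error oracle.
- *Surface S value*: decays uniform on the cell surface; an independent
  deterministic quadrature over the emission angle
  (`s_value_surface_quadrature`) agrees with the MC at 0.0195 Gy per decay
  for the default geometry.
- *Sphere profile*: concentric-shell scoring (5 um default) of a
  tumor-resident radial source (the penetration field, resampled onto a
  fine grid for inverse-CDF position sampling) plus a surrounding bath
  source, with per-shell standard errors.

Cell and nucleus radii (7.5/5 um) are representative epithelial values;
they are explicit `cell_geometry` parameters because the surface S value
depends strongly on them.

## 6. The dosimetry pipeline (`single_cell_dose`, `sterilization_diameter`)

A `therapy_scenario` bundles PK, binding model, labeling, and geometry.
`single_cell_dose` returns the two contributions for a suspended single
cell: the bath dose (cumulated decays × MC bath estimator, cell volume
excluded) and the self dose from surface-bound antibody (binding ODE
driven by the decaying bath concentration, integrated physical decays
while bound, times the surface S value).

`microtumor_dose_profile` combines the penetration field's decay density
with the bath source; `sterilization_diameter` scans diameters and reports
the largest whose summary dose reaches a threshold (default 10 Gy).
**Design decision:** the default summary statistic is the mass-weighted
*mean* dose over the tumor, the conventional output quantity for
microtumor dosimetry; the conservative profile *minimum* is available via
`statistic = "min"` and gives markedly smaller sterilization diameters for
tumors whose center lies beyond alpha reach of the penetration-limited
source. Both numbers are worth reporting for any real decision.

## 7. Outcome statistics (`fisher_exact`, `logrank`, ...)

The exact Fisher test sums hypergeometric probabilities no larger than the
observed table's, and the Mantel–Cox log-rank test is computed from first
principles over the risk sets; both are verified against independent
implementations (`stats::fisher.test`, `survival::survdiff`) in the test
suite. Tumor-free percentages are displayed with half values rounding
down, matching conventional lab reporting of e.g. 20/22 as 91%.
`decompose_dual_label` solves the 2×2 spillover system of dual-isotope
gamma counting with decay correction; `residence_time_and_organ_dose`
integrates measured organ fractions with exponential-trapezoid segments, a
leading ramp, and an analytic physical-decay tail, then converts to an
alpha-only, locally deposited organ dose.

## 8. Synthetic data generators (`gen_*`)

Every generator returns `(observations, truth, config)` with all
randomness derived from the config seed, so estimators can be validated
against known ground truth. Scope: binding time courses (forward model ×
log-normal noise), microtumor cohorts (truncated log-normal radii on
[19, 82] um; cells = 1.74e-4 · (4π/3) r³, a packing chosen so that radius
range corresponds to ~5–400 cells; activity linear in cell number),
four-arm therapy outcomes (Bernoulli cure status, uniform death days on
[90, 154]), and biodistribution tables (bi-exponential organ templates for
three tracers, with the free-astatide tracer showing the late thyroid and
stomach rise). The generators emulate measured-data *structure*; the
therapy death-day distribution in particular is statistical plumbing, not
a calibrated survival model.

## 9. Known limitations

- Track physics omits energy-loss straggling and delta rays; dose at shell
  boundaries is exact only in the CSDA sense.
- Binding has no internalization, shedding, or metabolic degradation of
  the label; the in-vivo single-cell trajectory assumes no local ligand
  depletion.
- The penetration model treats tissue as homogeneous and spherically
  symmetric with a constant diffusivity.
- Patient-scenario PK neglects biological clearance entirely (λ_bio = 0).
- The single-cell bound dose is sensitive to the assumed surface
  occupancy; the full kinetic model reaches ~230,000 bound antibodies per
  cell near equilibrium, while assay-measured occupancies (and apparent
  immunoreactive fractions well below 1) suggest smaller effective values.
  The package computes the model value and leaves any immunoreactivity
  scaling to the caller.
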