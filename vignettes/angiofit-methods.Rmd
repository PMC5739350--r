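---
title: "angiofit: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{angiofit: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: what the model
assumes, where each parameter comes from, which conventions were chosen
where several were defensible, and what the synthetic-data tests do and
do not demonstrate about real data.

## The compartmental model

The mouse is represented by three well-mixed compartments: **normal
tissue** (skeletal muscle), **blood** (plasma), and **tumor**.  Molecular
species comprise four VEGF isoforms — mouse VEGF120/VEGF164 secreted by
endothelial cells and muscle fibers, human VEGF121/VEGF165 secreted by
the xenografted tumor cells — the receptors VEGFR1 and VEGFR2 and
co-receptors NRP1/NRP2 on muscle fibers, endothelial cells, and tumor
cells; soluble VEGFR1; the plasma protease inhibitor
alpha-2-macroglobulin; glycosaminoglycan (GAG) chains standing in for
extracellular-matrix binding; and the anti-VEGF antibody.

`build_network()` expands a configuration into explicit mass-action
species and elementary reactions by rule:

* every isoform binds VEGFR1 and VEGFR2;
* the heparin-binding isoforms (VEGF164/165) additionally bind NRPs and
  GAG sites;
* NRPs couple to VEGFR1/VEGFR2 on the same membrane and VEGF binds the
  pre-coupled complex (ternary complexes), from either side for
  heparin-binding isoforms;
* all cell-surface species internalize at a first-order rate; receptor
  surface densities are maintained by insertion balancing
  internalization, and newly formed tumor tissue carries receptors at
  the specified density;
* plasma species clear; tissues exchange mobile species with plasma via
  permeability-surface products and the normal interstitium additionally
  drains to blood by lymph flow.

A receptor given surface density zero generates no species and no
reactions, so grammar variants are controlled purely by configuration.
NRP2 is part of the grammar but its default density is zero everywhere:
the pro-angiogenic inventory is defined with NRP1 (see below), the
source analyses do not separate NRP2's role, and omitting it keeps the
default state vector (163 species) lean enough for the tens of
thousands of integrations the fitting and sensitivity pipelines need.
Setting any NRP2 density in the config restores the full grammar, and a
flag (`rules$ang_include_nrp2`) controls whether NRP2-containing ternary
complexes count toward the angiogenic signal (default: they do not).

**Units.** Time in seconds; volumes in cm³; tissue species in mol/cm³
total tissue, blood species in mol/cm³ plasma.  Fluid-phase bimolecular
rate constants are configured in M⁻¹s⁻¹ and converted internally
(1 M⁻¹ = 1000 cm³/mol); reactions in interstitial fluid are scaled by
the compartment's accessible fluid fraction, surface–surface coupling
constants are configured directly in (mol/cm³ tissue)⁻¹s⁻¹.
Inter-compartment fluxes exchange moles, converted through the explicit
compartment volumes, so transport is conservative by construction.

**Tumor geometry.**  The tumor is partitioned into vascular space
(constant fraction, default 0.04), interstitial space, and tumor cells.
The interstitial fraction decays exponentially with total volume,
`f_int(V) = f_min + (f0 − f_min) exp(−λV)` (defaults 0.25, 0.50,
1.2 cm⁻³), capturing the measured increase of cell density during
xenograft growth; the cell fraction is the remainder, and the cell count
uses a 905 µm³ tumor-cell volume.  Tumor growth dilutes all tumor-
compartment species (`−C · V̇/V`), which preserves amounts exactly;
maintained densities (receptors, matrix sites) are replenished in
proportion.

## The growth law and the angiogenic signal

Tumor volume obeys a Simeoni-type law that switches smoothly from
exponential growth at rate `k0` to linear growth at rate `k1`
(sharpness `psi`, held at 20 throughout), multiplied by `Ang(t)/Ang0`:
the ratio of the current angiogenic signal to its basal value.
`Ang(t)` sums the tumor-endothelial complexes that contain one VEGF
isoform bound to VEGFR1 or VEGFR2, with or without NRP1 — free
receptors, NRP-only, GAG-bound, soluble-receptor-bound and drug-bound
VEGF are excluded.  A second variant multiplies by
`1 − (Ang0 − C_Ang·Ang)/Ang0`; algebraically this equals
`C_Ang·Ang/Ang0`, which is why `C_Ang` and `Ang0` cannot be estimated
jointly — the variant is provided for simulation but never fitted by
default.  The Simeoni denominator is evaluated in the log domain so
`(k0 V/k1)^psi` cannot overflow at `psi = 50`.

Growth is coupled to the species system as one additional state, with
`Ang` read from the live state at every step (no lag).  The model
deliberately has no plateau term: saturating/sigmoidal growth curves are
outside its scope, and no drug kill-rate enters the growth law —
treatment acts only through the angiogenic signal.

## Initialization

Species are initialized at the drug-free steady state of the
fixed-volume system at `V(0)` (integration until the angiogenic signal's
drift falls below 1e-4 relative per checkpoint interval), after which
the coupled system is released.  Steady-state initialization removes
secretion/binding transients that would otherwise contaminate the early
growth curve, and it defines the basal signal: `Ang0 = NULL` in the
configuration resolves to the computed basal `Ang`.  With the default
parameterization the basal signal is ≈ 2.2×10⁻¹⁵ mol/cm³, inside the
1e-16..1e-14 uncertainty range used for fitting and sensitivity
analysis.

## Parameter provenance

Values printed in the source study and used verbatim: `psi = 20`; the
fitting bounds (1e-8..1e-2 for `k0`, `k1`; 1e-16..1e-14 for `Ang0`); the
eFAST range 0.1..50 for `psi`; 30 multistart fits; the 0.1 cm³ treatment
threshold; twice-weekly one-minute infusions at 2 and 10 mg/kg for six
weeks; drug `k_on = 5.4e4 M⁻¹s⁻¹`, `k_off = 2.19e-5 s⁻¹`, clearance
`5.73e-7 s⁻¹`; the 905 µm³ tumor-cell volume.  The same source also
prints a drug affinity of 4456 pM, which is inconsistent with
`k_off/k_on ≈ 406 pM`; the rate constants are what the ODEs need, so
they are used as printed and the conflicting affinity is recorded in the
configuration (`drug$affinity_reported_pM`) without overriding them.

Everything else — compartment volumes, cell densities, receptor surface
densities, binding/coupling/internalization rates, secretion, transport
and clearance rates — belongs to the underlying whole-body model, whose
tables are not in the main text.  These live in `default_config()` as
package defaults at literature-plausible magnitudes (e.g. VEGF–VEGFR
dissociation constants in the 3–20 pM effective range, interstitial VEGF
in the tens of femtomolar, receptor densities of 10³–2×10⁴ per cell) and
are flagged as defaults, not source values.  Two calibrations were made
once, during model construction, and frozen: tumor-cell secretion rates
set so the basal angiogenic signal falls inside the `Ang0` fitting
range, and antibody permeability (with drug–VEGF complexes permeating
like free antibody, so tissue-captured VEGF can reach plasma and be
cleared) set so the standard doses produce a clearly dose-separated
response (RTV ≈ 0.87 at 2 mg/kg, ≈ 0.60 at 10 mg/kg on the default
growth parameters).  Without complex transport an antibody only buffers
VEGF: at steady state the secretion flux must still exit through
receptor internalization, so free VEGF — and the angiogenic signal —
would return to baseline between doses.

Whether the antibody extravasates into tissue interstitia at all is
toggleable (`drug$extravasate`, default on).

## Fitting protocol and identifiability

`sum_squared_residuals()` is the unweighted SSR between measured and
simulated volumes at the exact measurement times (weighting the
residuals is deliberately not offered).  `fit_dataset()` runs bounded
Levenberg–Marquardt in log10 parameter space from `n_starts = 30`
log-uniform starting points, each drawn from a run-indexed seed so the
whole ensemble is bit-reproducible; a simulation failure inside the
objective returns a large finite penalty (1e12 plus a bound-distance
term) and is logged, so the optimizer continues.  `select_best_fits()`
keeps runs with SSR within 10% of the minimum — the selection rule the
source leaves unstated, made explicit and stored with its tolerance.

**A structural non-identifiability shapes the default protocol.**  The
growth rate is exactly invariant under
`(k0, k1, Ang0) → (c·k0, c·k1, c·Ang0)`: the Simeoni factor is
homogeneous of degree one in `(k0, k1)` and `Ang0` enters only as a
divisor of a signal that does not itself depend on the growth
parameters.  Fitting all three therefore identifies them only up to a
ray, bounded by the `Ang0` box — individual estimates of `k0` and `k1`
are then arbitrary within about two orders of magnitude.  The package's
default consequently frees `{k0, k1}` and holds `Ang0` at the
model-computed basal signal, which is also the physically consistent
reading of "basal": it is a property of the VEGF network, not a free
dial.  The original three-parameter protocol remains available
(`free = c("k0", "k1", "Ang0")`) for users who want to reproduce it,
degeneracy and all.

**Confidence bands.**  The source does not state how its 95% intervals
were constructed.  Percentile bands across multistart members are
implemented (`method = "members"`) but collapse when every start
converges to the same optimum, so the default is covariance-based: the
linearized least-squares covariance `σ̂²(JᵀJ)⁻¹` at the best fit (log10
space), inflated by the small-sample factor
`sqrt(p·F(0.95; p, n−p)/χ²(0.95; p))`, is sampled and the pointwise
2.5th/97.5th percentiles of the simulated volumes form the band.  On
synthetic cohorts (12 weekly points, 5% noise) these bands cover the
true noiseless curve at ≈ 90% of time points on average.  Fitting only
pre-treatment measurements yields visibly wider bands than fitting the
full curve, as expected.

**Comparisons across datasets** use the Kruskal–Wallis rank test
(omnibus, then pairwise two-group tests) with Benjamini–Hochberg FDR
adjustment and the significance bins ≤0.001, ≤0.01, <0.05.

## eFAST

`efast_design()` implements the extended FAST search curves
`x(s) = min + (max − min)(1/2 + arcsin(sin(ωs + φ))/π)` with `NS`
points of `s` spanning one period, random phases per resample, and a
dummy parameter appended.  Decade-spanning ranges (`k0`, `k1`, `Ang0`)
are sampled in log10 space; `psi` (0.1–50) linearly.  The interest
frequency is `ω_max = ⌊(NS−1)/(2·Mi)⌋`, so the `Mi` harmonics used by
the first-order index reach the Nyquist limit exactly; the
complementary factors cycle through frequencies
`2..⌊ω_max/(2·Mi)⌋`.  Frequency 1 is deliberately excluded from the
complementary set: a factor that traverses its range once per curve
makes the along-curve variance — the denominator of the total-order
index — fluctuate strongly between phase draws.  On the Ishigami
benchmark at NS = 257, Mi = 4, five resamples, this recipe keeps every
total-order index within 0.05 of its analytic value, whereas a
frequency-1 complementary assignment errs by up to ~0.15.  The
constraint `NS ≥ 16·Mi + 1` is enforced with the minimum stated in the
error.

`run_efast_on_model()` evaluates the untreated tumor volume at the
final simulated time (eight weeks by default; any set of output times
can be requested) over the design, reusing the one steady state the
growth parameters cannot affect.  Total-order indices for `k0`, `k1`
and `Ang0` exceed the 0.4 screening cutoff while `psi` and the dummy
do not — the rationale for fixing `psi` and fitting the other three
(here: two, with `Ang0` pinned to the basal signal).  Significance
against the dummy uses a rank-sum test across resamples.  The absolute
index values wobble by a few hundredths with the phase seed; that
spread is estimator noise, and the dummy's nonzero index (~0.1) is the
same leakage floor, which is why significance is judged against it
rather than against zero.

## PLSR

`nipals_fit()` autoscales X and Y (the predictors span eight orders of
magnitude, so unscaled PLSR would be meaningless; `k0`, `k1`, `Ang0`
and `k0/k1` are log10-transformed before scaling in the pipeline
tests), iterates NIPALS to 1e-12 with a 500-iteration cap, deflates
both blocks per component, and fixes each component's sign so its
largest-magnitude weight is positive — outputs are reproducible to the
sign.  `plsr_metrics()` computes `Q²Y = 1 − PRESS/TSS` by leave-one-out
with centering and scaling re-estimated inside each fold (the
convention is pinned by a regression test against the fixed-scaling
variant).  VIP scores use the standard weighted-variance form; their
squares average to one identically.  A model-selection sweep over
component counts and predictor subsets is a report generator
(`plsr_model_sweep()`), not an automatic selector.

One caveat worth stating: with one latent component, a response equal
to one predictor column is reproduced exactly only when the scaled
predictors are orthogonal — the first weight vector is `Xᵀy`, not a
unit basis vector.  The exact-fit property in general requires full
rank.

## Synthetic data

`generate_growth_dataset()` simulates control and treated arms with the
full mechanistic model at known growth parameters and observes
`V_obs = scale · V_true · exp(ε)`, `ε ~ N(0, log(1+CV))` —
multiplicative lognormal noise, because caliper error scales with tumor
size.  The `scale` tag encodes caliper volume-formula variants (for
example π/6·L·W·H vs L·W²/2), which rescale observed volumes without
changing dynamics; the fitting objective applies the dataset's tag to
the simulated volumes.  `preset_designs()` ships six templates that
differ in cadence (3.5–7 day spacing), initial volume (0.01–0.08 cm³),
noise CV (5–10%), dose (2 or 10 mg/kg), treatment start, and formula
tag; their true kinetics were chosen once so noise-free final control
volumes span roughly 0.9–2.1 cm³, matching the diversity of published
MDA-MB-231 xenograft studies.  Two templates provide at least three
strictly pre-treatment measurements to exercise the early-fitting
protocol.

What the generator does **not** emulate: animal-to-animal random
effects (each dataset is one mean curve), censoring/dropout, sigmoidal
or plateauing growth, and vascular remodeling under treatment.  Passing
the recovery and coverage tests therefore shows the pipeline is correct
and well-calibrated *for this model class*, not that real xenograft
curves obey it.

The recovery experiment (20 cohorts, 12 weekly measurements, 5% noise,
30-start fits) draws true kinetics log-uniformly from
k0 ∈ [8×10⁻⁷, 3×10⁻⁶] s⁻¹ and k1 ∈ [2×10⁻⁷, 8×10⁻⁷] cm³/s — inside
the fitting bounds and in the range that produces realistic
0.5–2.5 cm³ tumors over 11 weeks; drawing from the full six-decade
bounds would mostly produce flat or exploding curves that no weekly
design could inform.

## Numerical choices

* Integrator: `lsodes` (stiff, sparse-Jacobian) on a compiled C
  right-hand side; `rtol = 1e-6`, per-species `atol = 1e-22`,
  `atol = 1e-9` on the volume.  Halving tolerances or growing the
  output grid tenfold changes the final volume by far less than 0.1%.
  Conservation checks run at `rtol = 1e-11`.
* Nonnegativity: rates are evaluated with negative states clamped to
  zero, and output values in `[−1000·atol, 0)` are reported as 0;
  boundaries are never reflected.
* Infusions are exact segment boundaries: integration restarts at every
  window edge, so no dose is smeared by step control.  The drug mass
  balance (infused = free + complexed + cleared, with a cleared-pool
  bookkeeping species) closes to 1e-6 relative.
* `detect_t_start()` brackets the 0.1 cm³ crossing on the output grid
  and refines it by root-finding on re-integrations, to a 30 s time
  tolerance.
* Problem sizes in the test suite — 20 recovery cohorts, NS = 257 with
  five resamples for eFAST, a 5×5×3 receptor grid — are the package's
  desk-scale defaults; all are plain function arguments and scale up
  unchanged.

## Known limitations

Vascular density and permeability do not remodel under treatment; the
blood compartment's volume is fixed; intracellular signaling downstream
of receptor binding is not represented; growth cannot plateau; human
(patient-scale) geometry is out of scope.  The default parameterization
is a self-consistent placeholder for an unpublished table set — analyses
that depend on absolute concentrations (rather than relative responses)
should treat it as a starting point and substitute measured values via
the configuration.
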