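# angiofit

Mechanistic modeling of VEGF-gated tumor growth and the response to
anti-VEGF (bevacizumab) treatment in tumor-bearing mice.

## The problem

Anti-angiogenic drugs that neutralize vascular endothelial growth factor
(VEGF) help some tumors and not others, and no validated biomarker
predicts which.  One candidate predictor is the tumor's own growth
kinetics.  `angiofit` implements a whole-mouse systems pharmacology model
that makes this question quantitative: a three-compartment reaction
network (normal tissue, blood, tumor) tracks the kinetics and transport
of mouse and human VEGF isoforms, their receptors VEGFR1/VEGFR2, the
neuropilin co-receptors, soluble VEGFR1, matrix binding sites, and an
anti-VEGF antibody; the tumor compartment grows in proportion to the
**angiogenic signal** `Ang(t)` — the total concentration of VEGF-bound
VEGFR1/VEGFR2 complexes (with or without NRP1) on tumor endothelial
cells.

The tumor volume follows a Simeoni-type growth law gated by that signal:

    dV/dt = k0 V / [1 + (k0 V / k1)^psi]^(1/psi) * Ang(t)/Ang0

with exponential rate `k0` (s⁻¹), linear rate `k1` (cm³/s), transition
sharpness `psi` (held at 20), and basal signal `Ang0` (mol/cm³ tissue).
Treatment is simulated mechanistically: twice-weekly one-minute
intravenous infusions of an antibody that binds human VEGF
(k_on = 5.4×10⁴ M⁻¹s⁻¹, k_off = 2.19×10⁻⁵ s⁻¹, plasma clearance
5.73×10⁻⁷ s⁻¹), starting when the tumor reaches 0.1 cm³ (`T_start`).
Efficacy is summarized as the relative tumor volume
`RTV = V_treatment / V_control` six weeks after `T_start`.

Around that core the package provides the full analysis pipeline:

* `build_network()` / `simulate_model()` — rule-based network expansion
  and stiff ODE integration (compiled C right-hand side);
* `fit_problem()` / `fit_dataset()` / `select_best_fits()` /
  `confidence_band()` — multistart bounded least squares for the growth
  kinetics from xenograft growth curves;
* `relative_tumor_volume()`, `detect_t_start()`, `drug_mass_balance()` —
  treatment simulation;
* `run_efast_on_model()` — eFAST variance-based global sensitivity
  analysis with a dummy parameter;
* `nipals_fit()`, `plsr_metrics()`, `vip_scores()` — PLSR biomarker
  analysis (NIPALS, leave-one-out Q²Y, VIP);
* `compare_parameter_sets()` — Kruskal–Wallis comparisons with
  Benjamini–Hochberg correction;
* `receptor_response_grid()` — RTV maps over tumor-cell VEGFR1/VEGFR2/NRP
  surface densities;
* `generate_growth_dataset()` / `preset_designs()` — synthetic xenograft
  cohorts with known ground truth.

## Worked example

```r
library(angiofit)

cfg <- default_config()          # full parameterization, editable
net <- build_network(cfg)
net
#> angiofit reaction network
#>   species:   163 in 3 compartments
#>   reactions: 504
#>   transport edges: 16 | lymph edges: 12
#>   pro-angiogenic complexes: 16

ss <- steady_state(net)          # drug-free equilibrium at V0
attr(ss, "Ang")
#> 2.19e-15                        # basal angiogenic signal, mol/cm^3

relative_tumor_volume(net, dose = 10)
#> anti-VEGF treatment response
#>   dose: 10 mg/kg | T_start: 15.86 days
#>   V_control: 1.213 cm^3 | V_treatment: 0.724 cm^3
#>   RTV: 0.5969

# fit a synthetic xenograft dataset (true k0 = 1.4e-6, k1 = 3.5e-7)
des <- preset_designs()$slow_weekly
ds  <- generate_growth_dataset(net, des$true_growth, des,
                               noise_cv = des$noise_cv, seed = 7)
ens <- select_best_fits(fit_dataset(fit_problem(ds, net,
                                                n_starts = 30, seed = 1)))
ens
#> angiofit multistart fit: 6 runs, free parameters: k0, k1
#>   best SSR: 0.0054801 at k0 = 1.322e-06, k1 = 3.662e-07
#>   selected: 6 runs (tol 0.1)
```

Reading the output: the tumor reaches the 0.1 cm³ treatment threshold
after ~16 days; six weeks of twice-weekly 10 mg/kg dosing shrinks the
final volume to 60% of the untreated control (RTV < 1 means the drug
worked).  The 30-start fit recovers the generating kinetics of the noisy
synthetic dataset to within ~6% despite 8% multiplicative measurement
noise, and 6 of 30 starts land within 10% of the best error.

`vignettes/angiofit-methods.Rmd` documents the model assumptions, unit
conventions, parameter provenance, and numerical choices.

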