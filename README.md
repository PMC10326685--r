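# imatpbpk

A physiologically based pharmacokinetic (PBPK) simulator for steady-state
imatinib exposure in virtual adult populations, built for exposure–outcome
analyses in chronic myeloid leukemia (CML): who reaches the trough efficacy
target (~1 µg/mL), who is over-exposed, and which patient characteristics and
co-medications drive the difference.

Imatinib is a low-hepatic-extraction BCR-ABL tyrosine kinase inhibitor, so its
steady-state total plasma exposure is governed by plasma protein binding and
intrinsic hepatic clearance. The package implements the mechanisms that make
this interesting:

- **Saturable α1-acid glycoprotein (AAG) binding.** The unbound fraction
  `fu` solves the one-site equilibrium (quadratic in the unbound
  concentration); in the dilute limit `fu = 1 / (1 + [AAG]/K_d,app)`, with
  `K_d,app` calibrated so `fu = 0.05` at the reference AAG of 0.91 g/L. AAG
  is an acute-phase protein with several-fold interindividual variation, and
  `fu` inherits that variability.
- **Abundance-scaled hepatic clearance.** Unbound intrinsic clearance is
  `CLint_u = Σ_e abundance_e × activity_e × CLint_per_pmol_e × MPPGL × liver
  weight` plus P-gp/BCRP biliary clearance, fed into the well-stirred liver
  model `CLh = Q_h · fu_b · CLint_u / (Q_h + fu_b · CLint_u)`. Hepatic CYP3A4
  and CYP2C8 abundances are sampled from truncated log-normals (means
  93.0 and 22.4 pmol/mg) with Spearman correlation 0.68 via a Gaussian
  copula.
- **CYP3A4 autoinhibition.** Imatinib inactivates its own CYP3A4 pathway;
  enzyme activity follows the turnover model
  `de/dt = k_deg·s(t) − e·(k_deg + k_inact·Cu/(K_I + Cu))`, so apparent
  clearance falls from day 1 to day 14 and CYP3A4 modulators lose leverage at
  steady state.
- **Virtual populations and virtual twins.** Individuals are sampled from
  configurable covariate models (European/Chinese/Japanese ancestry,
  cirrhosis and renal-impairment multiplier tables, CKD-EPI eGFR); a
  patient record's observed covariates can be fixed while unobserved
  physiology is sampled ("virtual twin").
- **Study designs.** 10-trial × 10-subject virtual trials, one-at-a-time
  sensitivity sweeps, paired drug–drug interaction (DDI) studies with five
  CYP modulators (diltiazem, verapamil, hyperforin, trimethoprim,
  clopidogrel) summarised as geometric mean ratios (GMR) with 90% CIs and the
  0.80–1.25 no-effect rule, and a synthetic 68-patient cohort generator with
  logistic exposure→outcome links (early molecular response, grade ≥3
  adverse reactions).

The ODE core (depot, gut wall, flow-limited liver, central, peripheral, plus
enzyme-activity states and per-route elimination sinks) is compiled C driven
through `deSolve`, so a 14-day simulation takes ~10 ms and full study designs
run in seconds.

## Worked example

```r
library(imatpbpk)

cfg <- load_model_config()        # shipped drug/system/perpetrator config
ind <- sample_individual(cfg$system, cfg$drug,
                         list(age = 55, sex = "male", ancestry = "European"),
                         seed = 42)
sim <- simulate_pbpk(ind, cfg$drug, dose_regimen(400, 24, 14), cfg$system)
sim$metrics
#>   auc_0_24_ss css_max css_min cl_over_f
#> 1        31.7    1.88   0.865      12.6
```

This heavy (101 kg) 55-year-old with above-average CYP abundances clears
imatinib fast: his day-14 AUC over the dosing interval is 31.7 µg·h/mL
(CL/F 12.6 L/h) and his trough of 0.87 µg/mL sits *below* the ~1.0 µg/mL
efficacy target — the kind of subject the exposure–response analysis flags.

A paired interaction study with the weak CYP2C8 inhibitor trimethoprim
(300 mg daily, days 8–14) on the standard 10×10 design:

```r
ddi_study(cfg$drug, cfg$system, dose_regimen(400, 24, 14),
          cfg$perpetrators$trimethoprim,
          trial_design(n_trials = 10, n_subjects = 10, seed = 1))
#> <ddi_result> perpetrator 'trimethoprim' (90% CI)
#>   metric        gmr    lo    hi     n clinically_significant
#> 1 auc_0_24_ss 1.22  1.21  1.24    100 FALSE
#> 2 cl_over_f   0.818 0.809 0.826   100 FALSE
#> 3 css_max     1.16  1.16  1.17    100 FALSE
#> 4 css_min     1.30  1.28  1.32    100 TRUE
```

Steady-state AUC rises ~22% and the trough ~30%: because chronic imatinib
has already inactivated much of its CYP3A4 pathway, CYP2C8 inhibitors move
exposure more than the "moderate" CYP3A4 inhibitors do (try
`cfg$perpetrators$diltiazem`, whose AUC GMR is ≈1.05).

`autoplot()` methods draw concentration–time profiles (`pbpk_sim`), GMR
forest plots (`ddi_result`) and sweep summaries (`sweep_result`);
`tidy()`/`glance()` return tibbles for downstream work.

## Command line

A thin CLI over the same functions lives at `inst/cli/imatpbpk.R`
(subcommands `simulate-cohort`, `sensitivity`, `ddi`, `compare-outcomes`),
e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/imatpbpk.R", package="imatpbpk"))')" \
  ddi --perpetrator trimethoprim --seed 1 --out-dir out/
```
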