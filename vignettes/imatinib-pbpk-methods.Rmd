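---
title: "Model and methods: steady-state imatinib PBPK simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: steady-state imatinib PBPK simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
disposition model and its assumptions, the parameters that matter, what the
synthetic data emulate (and do not), and the numerical and design choices
made where the design was genuinely open.

## The disposition model

Imatinib is an orally dosed, low-hepatic-extraction base whose steady-state
total plasma exposure is controlled by plasma protein binding and intrinsic
hepatic clearance. The simulator integrates a deliberately minimal whole-body
system:

* an **oral depot** with first-order absorption (`ka`, 1/h) and a fraction
  absorbed `fa`;
* a **gut wall** compartment through which absorbed drug transits
  (`gut_transit`, 1/h) in competition with a small enterocyte CYP3A4
  clearance, so gut availability `Fg` is emergent rather than imposed;
* a **flow-limited, well-stirred liver**: venous outflow concentration
  `C_out = (A_L/V_L)/Kp_L`, metabolism and biliary efflux act on the unbound
  outflow concentration `fu · C_out`. At steady state this reproduces the
  well-stirred clearance `CLh = Qh · fu_b · CLint_u/(Qh + fu_b · CLint_u)`
  exactly, and oral first-pass extraction emerges from routing absorbed drug
  through the liver;
* lumped **central** and **peripheral** distribution volumes (`vc_per_kg`,
  `vp_per_kg`, inter-compartmental clearance `q_inter`) standing in for the
  full tissue list of a commercial simulator — every reported output is a
  plasma metric, so tissue-level resolution is unobservable here;
* cumulative **elimination sinks** per route (CYP3A4, CYP2C8, other CYPs,
  biliary, renal, gut wall, unabsorbed), which make the mass-balance
  invariant testable: compartments plus sinks must equal the administered
  dose to within 0.1% on every simulation.

Dosing is handled as solver events that increment the depot (no
delta-function approximation); the stiff `lsoda` integrator runs at relative
tolerance `1e-8` and absolute tolerance `1e-10` mg by default, and the test
suite checks that a 100-fold loosening changes the steady-state AUC by less
than 0.1%.

### Saturable AAG binding

Total plasma concentration `C` and unbound concentration `Cu` are related by
one-site binding to α1-acid glycoprotein (AAG):

`Cu + Bmax·Cu/(Kd + Cu) = C`,

solved in closed form (physical root of the quadratic) at every right-hand-side
evaluation. `Bmax` is the AAG concentration converted to drug-equivalent
binding capacity through the molecular weights (44 kDa for AAG, one site per
molecule by default — the stoichiometry is not an observable of this
analysis, so it is a config constant). The apparent dissociation constant is
*calibrated*, not measured: `kd_app = aag_ref·fu_ref/(1−fu_ref)` makes the
dilute-limit unbound fraction exactly `fu_ref = 0.05` at the reference AAG of
0.91 g/L. At therapeutic concentrations (peaks of ~3 µg/mL ≈ 6 µM against
~21 µM of binding sites at reference AAG) binding saturates appreciably, and
this concentration dependence is what makes trough concentrations more
sensitive than AUC to every clearance-side perturbation.

### Enzyme turnover and autoinhibition

Hepatic CYP3A4, gut CYP3A4 and hepatic CYP2C8 activities are state variables
with turnover dynamics `de/dt = kdeg·s(t) − e·(kdeg + k_obs)`, where `s(t)`
carries induction and `k_obs` mechanism-based inactivation
(`kinact·Cu/(KI + Cu)`). Imatinib inactivates CYP3A4; its `KI` (0.05 µM
unbound) and `kinact` (0.03/h) are calibration constants chosen jointly with
the pathway split (below), placing the inactivation near saturation at
therapeutic unbound concentrations with a steady-state activity of roughly
0.4. Two consequences follow and both are tested: apparent oral clearance
falls from day 1 to day 14, and CYP3A4 modulators move steady-state exposure
far less than their single-dose reputation suggests. The degradation
constants (`0.0158`/h hepatic, `0.03`/h gut) are literature-typical turnover
values.

Perpetrators are analytic one-compartment oral forcing functions (closed-form
superposition over doses; a formed metabolite follows a Bateman cascade),
not co-integrated states: their interaction leverage enters only through
unbound concentration at the enzyme site, so simple PK with apparent `V/F`,
`CL/F` and `fu` suffices. Competitive inhibition divides enzyme activity by
`1 + Cu/Ki` instantaneously; MBI and induction act through the turnover
states. Gut-site drivers use the perpetrator's systemic unbound
concentration; likewise imatinib's own gut CYP3A4 inactivation is driven by
systemic unbound drug rather than the transient enterocyte concentration,
which would otherwise annihilate gut enzyme activity during every absorption
window for a drug with negligible enterocyte metabolism.

### Clearance composition

Unbound intrinsic clearance scales per pathway as
`abundance × activity × CLint_per_pmol × MPPGL × liver weight` plus
transporter-abundance-scaled biliary clearance. The per-pmol constants are
calibrated against the printed behaviour of the system rather than
transcribed from in-vitro tables (which are not reproduced in the source
material): the constraints are the 3% non-CYP3A4/2C8 metabolic share at
reference abundances, a typical-adult steady-state CL/F of 9–10.5 L/h at
400 mg daily, a trough near the ~1 µg/mL efficacy target, and the
sensitivity-sweep magnitudes. At steady state the resulting split of total
elimination is approximately: CYP2C8 ~50%, autoinhibited CYP3A4 ~15%,
other CYPs ~3% of metabolism, biliary (P-gp/BCRP) ~15%, renal ~17%.

Renal clearance is a composite:
`CL_R = cl_renal_ref · (eGFR/eGFR_ref) · (w·fu/fu_ref + (1−w))` with
`w = 0.8`. The filtration-like part scales with the unbound fraction; the
remainder represents capacity-limited tubular secretion of an avidly
transported base, which is insensitive to plasma binding. A pure
filtration-only scaling was considered and rejected: if *every* clearance
pathway scales with `fu`, the AAG sweep can only reproduce the dilute-limit
`fu` ratio (~9.3-fold over 0.3→3.2 g/L), and no CYP-insensitive clearance
remains to absorb what the CYP2C8/CYP3A4 sweeps leave unexplained. The
reference value (1.9 L/h at eGFR 100) stays within the range reported for
imatinib.

A deliberate consequence of this budget is that biliary efflux carries a
larger share (~15%) than a literal reading of "transporter abundance does
not matter" would suggest; transporter-abundance sweeps over modest ranges
remain statistically flat at the study's trial sizes, but extreme transporter
overexpression would matter in this model.

## Virtual populations

Covariate models are intentionally simple and fully config-visible:

* body size from ancestry/sex-specific normals (truncated at plausible
  floors); BSA by Du Bois;
* liver weight `∝ BSA^2.05` with a 0.3%/year decline after age 20 and a 15%
  CV log-normal residual. The exponent is calibrated so that the 45→125 kg
  body-weight sweep reproduces the printed ~44% AUC decrease — a steeper
  body-size dependence than anatomical liver mass alone, standing in for the
  joint scaling of liver mass, enzyme content and flows with size;
* hepatic blood flow `∝ BSA` with a 0.4%/year decline after 20;
* MPPGL log-normal (mean 40 mg/g, CV 30%);
* hepatic CYP3A4 (mean 93.0 pmol/mg, range 0–600) and CYP2C8
  (22.4 pmol/mg, 0–85) from truncated log-normals coupled by a Gaussian
  copula whose latent correlation `2·sin(π·ρ_s/6)` induces the target
  Spearman 0.68; marginals are preserved by inverse-CDF transforms of the
  truncated distributions;
* AAG by ancestry and sex (Asian < European, male > female), truncated to
  the healthy range 0.36–1.46 g/L; sweeps may override beyond it;
* serum creatinine by sex, eGFR by the 2009 CKD-EPI creatinine equation
  (original published constants, no ancestry coefficient);
* cirrhosis (Child–Pugh A/B/C) and renal bands as single named multiplier
  tables on liver weight, hepatic flow, CYP abundances and AAG — the
  severity grading reproduces the qualitative pattern (A mild, B/C
  substantial exposure increases; renal impairment raises exposure through
  acute-phase AAG elevation plus reduced CYP abundances, with a "modified"
  mode restoring healthy CYP abundances).

Virtual twins fix a record's observed covariates (age, sex, ancestry,
weight, height, creatinine, cirrhosis) and sample only the unobserved
physiology; missing weight/height are imputed at the ancestry/sex
distribution centres (the imputation rule is this package's choice — the
source material does not state one).

Randomness uses one root seed with per-subject substreams derived by a
counter scheme, so trial composition is reproducible and paired designs
(with/without perpetrator) share physiology exactly — GMRs of a null
perpetrator are 1 to machine precision.

## The synthetic cohort

`generate_cohort()` emulates the covariate envelope of a real-world CML
cohort (n = 68, ages 20–91, ~40% female, majority European with Chinese and
Japanese minorities, once-daily dosing mostly at 400 mg with some
300/600/800, rare cirrhosis, occasional co-medication with the five modeled
perpetrators). The marginal distributions are documented stand-ins — not
estimates of any real cohort's joint distribution — and that is the main
limit on external validity: passing tests show the *pipeline* detects an
exposure–outcome link of the encoded strength at these sample sizes, not
that real patients behave this way.

Outcome labels are Bernoulli draws from logistic links on log steady-state
AUC. Slopes are positive (the observed directions: achievers of early
molecular response and patients with grade ≥3 toxicity both sit higher in
exposure). Intercepts are calibrated so expected prevalences match 35/45
(EMR among evaluable) and 47/68 (ADR); the EMR slope (5 per log-AUC) is the
smallest round value at which the n = 68 design detects the contrast in at
least 90% of replications, the power the study design calls for.

## Numerical choices and degenerate inputs

* Steady-state metrics are taken on the 14th dosing interval (312–336 h);
  the trough is the end-of-interval (pre-dose) concentration. The output
  grid is 0.1 h over that interval (241 points), trapezoid AUC.
* The binding quadratic is solved in its numerically stable form
  (`0.5·(−b + sqrt(b² + 4·Kd·C))`); `fu` is clamped to `[1e−12, 1]`.
* Zero doses, zero abundances and zero intrinsic clearances are all valid
  inputs (they exercise the trivial limits in the test suite); a perpetrator
  regimen that does not fit inside the victim's window is a validation
  error, as is stacking two special-population conditions.
* With autoinhibition and saturable binding disabled the system is linear:
  dose-proportionality is exact to solver precision and the single-dose AUC
  matches the closed form `fa·Fg·Fh·D/(CLh + CL_R)` to <1%, which is the
  engine's primary correctness oracle.

## Known limitations

* No mechanistic absorption model, no enterohepatic recirculation, no
  transporter-mediated DDIs at the gut apical membrane; the N-desmethyl
  metabolite is tracked only as an elimination flux, not simulated in
  plasma; intracellular (target-cell) concentrations are out of scope.
* Perpetrator interaction constants are net effective values calibrated to
  the printed steady-state interaction magnitudes under the one-compartment
  forcing-function PK; they are not transferable in-vitro constants, and
  diltiazem/verapamil subsume their active metabolites into the parent's
  constants.
* The hepatic-extraction premise (`CLh/Qh < 0.3`) holds for the bulk of the
  population but can be exceeded in the joint tail of high abundance, high
  MPPGL and low AAG; the apparent terminal half-life exceeds the effective
  (accumulation-relevant) half-life because binding desaturates as
  concentrations fall.
* Enzyme abundance means are shared across ancestries (body size and AAG
  differ); pharmacogenetic variation (e.g. CYP2C8 alleles) is not simulated.

## Session-scale choices

Study designs default to 10 trials × 10 subjects; the outcome-comparison
analysis uses 100 seeded cohorts of 68 patients. With the compiled core a
14-day simulation costs ~10 ms, so the full acceptance analysis (11
end-points) runs in well under a minute and the complete test suite in a few
minutes.
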