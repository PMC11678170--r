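# secumipd

Model-informed precision dosing (MIPD) of subcutaneous secukinumab in
chronic plaque psoriasis.

Secukinumab is an anti-IL-17A monoclonal antibody dosed at 300 mg every 4
weeks during maintenance. In practice dermatologists *optimize* (less drug:
lower dose or longer interval) or *intensify* (more drug) that schedule
patient by patient. `secumipd` supports that decision with a population
PK/PD model and Bayesian individual estimation: from a patient's routine
drug levels and PASI scores it computes, for each candidate regimen, the
probability that the patient holds PASI ≤ 1 at the 20th maintenance cycle,
and recommends the most economical regimen still meeting a 90% probability
target.

## The model

* **PK** — two-compartment disposition with first-order SC absorption:
  CL 0.19 L/day, V2 3.61 L, V3 2.87 L, allometric weight scaling
  (CL ∝ WT^0.8, V2 ∝ WT) around 70 kg. The intercompartmental clearance is
  calibrated so the terminal half-life is exactly 27 days.
* **PD** — indirect response for PASI: zero-order lesion production kin
  inhibited by an Imax model (Imax 1.19, IC50 9.35 mg/L, production floored
  at zero), first-order remission kout 0.11/day, a four-compartment prePASI
  transit chain delaying the effect, and a three-mediator tolerance loop
  (kout_tol 0.003/day) that attenuates the drug effect in tolerance-prone
  patients.
* **Baseline** — B2 method: the individual baseline is the observed
  baseline times exp(eta_RV), with var(eta_RV) tied to the residual error
  variance (0.76² on the log scale).
* **Individual estimation** — MAP and random-walk Metropolis-Hastings over
  the log-scale random effects (kout, Imax, baseline, plus the tolerance
  rate where active), targeting p(y|psi)p(psi).
* **Decision** — 100 conditional "clones" per patient are simulated through
  10 cycles of the current regimen plus 10 cycles of each candidate
  (150/300 mg × q2w/q4w/q5w/q6w, 7 candidates); a regimen qualifies when
  ≥ 90% of clones have PASI ≤ 1 at cycle 20, and the most optimized
  qualifier (lowest annualized dose) wins.

No patient-level data are public, so the package ships a synthetic-cohort
generator reproducing the study's covariate distributions, sampling design
and regimen mix (22 patients, weight 74.5 ± 15 kg in 46-97, baseline PASI
11.6 ± 5.8 in 2-27.5, 4 tolerance-active patients).

## Worked example

```r
library(secumipd)

pop <- default_population()         # published PK/PD estimates
pop$pk_typical$q                    # 0.3032694  (Q calibrated to t1/2 = 27 d)

# a 22-patient virtual cohort with simulated TDM data
cohort <- generate_cohort(cohort_spec(), pop, seed = 42)
obs    <- simulate_trial(cohort, pop, seed = 43)

# MIPD for the first patient (current regimen: 300 mg q6w)
res <- run_mipd_patient(obs[[1]], cohort[[1]]$regimen, pop,
                        mipd_config(), seed = 7)
res$table[, c("regimen", "prob10", "prob20", "trough20")]
#>   regimen prob10 prob20  trough20
#> 1 300 q2w     37    100 55.949701
#> 2 300 q4w     37    100 22.313758
#> 3 300 q5w     37     80 15.806522
#> 4 300 q6w     37     37 11.686032
#> 5 150 q4w     37     31 11.159425
#> 6 150 q5w     37     14  7.903629
#> 7 150 q6w     37      5  5.843069
res$recommendation
#> MIPD recommendation (patient 1)
#>   current 300 q6w -> 300 q4w [intensified], P(PASI<=1 at cycle 20) = 100%
```

Reading: under the patient's own 300 mg q6w regimen only 37% of the
conditional clones reach PASI ≤ 1 (columns `prob10`, evaluated at cycle 10,
and the q6w row at cycle 20), so the current regimen fails the 90% rule;
both 300 q2w and 300 q4w reach 100%, and the less intense of the two —
300 mg q4w — is recommended, an *intensification* relative to q6w.
`trough20` is the steady-state trough concentration (mg/L) under each
candidate.

Cost arithmetic for the headline optimization (q4w → q5w):

```r
annual_cost(regimen(300, 5))
#> $doses_per_year
#> [1] 11
#> $cost_eur
#> [1] 13717
#> $savings_percent
#> [1] 21
```

Eleven annual doses instead of fourteen, EUR 13 717 per patient-year, a
21% saving at EUR 1246.98 per pre-filled syringe.

## Package layout

| | |
|---|---|
| `pk_parameters`, `scale_pk_allometric`, `terminal_half_life`, `calibrate_q_to_half_life` | PK parameter set and disposition algebra |
| `pd_parameters`, `inhibition_multiplier`, `initial_state` | PD turnover model |
| `simulate_pkpd`, `simulate_pasi`, `pk_profile`, `trough_concentration` | trajectory simulation (compiled ODE + closed-form PK) |
| `default_population`, `sample_individual`, `b2_baseline`, `apply_residual`, `write_population`/`read_population` | population model and JSON configuration |
| `observation_set`, `log_likelihood`, `log_prior`, `map_estimate`, `sample_conditional` | individual Bayesian estimation |
| `candidate_regimens`, `simulate_clones`, `probability_table`, `select_regimen`, `classify_regimen`, `annual_cost`, `exposure_response_window` | MIPD decision layer |
| `cohort_spec`, `generate_cohort`, `sampling_design`, `simulate_trial`, `scenario_preset`, `run_scenario_cohort` | synthetic cohorts |
| `read_dataset`, `write_dataset`, `pcvpc`, `mipd_config`, `run_mipd_patient`, `run_mipd_cohort`, `write_mipd_run` | I/O, diagnostics, pipeline |

See `vignettes/secumipd-methods.Rmd` for the full model description, the
numerical choices and the known limitations.
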