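# acsstrial

Design and simulation toolkit for randomised trials comparing non-antibiotic
with antibiotic treatment of **uncomplicated acute cystitis (uAC)** in women,
built around the Acute Cystitis Symptom Score (ACSS) as the patient-reported
outcome measure.

Because antibiotics and non-antibiotic agents act by different mechanisms —
and because asymptomatic bacteriuria after clinical recovery may even protect
against recurrence — bacterial eradication cannot serve as the primary
endpoint of such a trial. The clinical outcome, measured with a validated
symptom score, has to carry the primary analysis, with microbiology
evaluated alongside. `acsstrial` implements that methodology end to end, for
trial statisticians and methodologists:

* **ACSS scoring** — 18 ordinal/boolean items in Typical, Differential, QoL
  and Additional domains (severities 0–3); nested symptom-set variants of
  the typical domain: EMA3 ⊂ FDA4 ⊂ ACSS5 ⊂ ACSS6.
* **Eligibility** — the recommended enrolment rule: typical summary score
  S ≥ 6 with at least one symptom more than mild (max severity ≥ 2) plus
  documented pyuria (≥ 10 WBC/mm³), each component switchable.
* **Bacteriuria significance** — four policies, from the classical
  10⁵ CFU/mL cut-off to the species-aware rule (*E. coli* significant at
  any count; enterococci and group B streptococci never).
* **Outcome adjudication** — visit windows (early 2–4 d, end of treatment
  5–9 d, test of cure 5–7 d after end of treatment, late follow-up
  24–33 d) and five cure thresholds. The favoured one declares cure iff
  S₅ ≤ 5, no symptom > mild, and no visible blood; its complement is
  exactly the failure rule S₅ ≥ 6 ∨ max ≥ 2. Rescue antibiotic therapy is
  always failure.
* **Diagnostic accuracy** — sensitivity, specificity, PPV/NPV, LR±,
  diagnostic odds ratio, Youden index J = Se + Sp − 1, rank
  (Mann–Whitney) AUC, phi; Wilson and log-normal intervals;
  Haldane 0.5 correction for zero cells.
* **Non-inferiority** — risk difference Δ = p_test − p_ref at test of cure
  with Newcombe hybrid Wilson score interval (Wald and Miettinen–Nurminen
  selectable); non-inferior iff the lower confidence bound lies strictly
  above the −10 % margin; nested ITT / clinical-ITT / micro-ITT
  populations.
* **Synthetic cohorts** — seeded generators for a 517-subject
  case/control diagnostic study (285 cases / 232 controls) and a
  134-patient two-arm outcome trial, plus a Monte-Carlo recovery harness;
  every pipeline stage is exercisable with no external data.

## Worked example

```r
library(acsstrial)

baseline <- acss_response(c(2, 2, 1, 1, 1, 0), patient_id = "p001")
score_domain(baseline, "typical")
#> [1] 7

enroll(baseline, urine_result("p001", 0, wbc = 25), diagnostic_rule())
#> ELIGIBLE
#>   [pass] summary score ACSS6 >= 6 (observed 7)
#>   [pass] at least one symptom more than mild (max severity 2)
#>   [pass] pyuria >= 10 WBC/mm3 (observed 25)
```

The patient scores 7 on the six typical symptoms with two moderate
symptoms and pyuria, so she enters the trial. At the test-of-cure visit
(day 11; 6 days after the end of a 5-day treatment) her follow-up response
is adjudicated:

```r
fu <- acss_response(c(1, 0, 1, 0, 0, 0), part = "B", visit_day = 11,
                    dynamics = 1, patient_id = "p001")
adjudicate(fu, "ACSS5")
#> Adjudication: SUCCESS
```

Score 2, nothing worse than mild, no visible blood: clinical cure. A whole
simulated trial, from screening through the primary analysis:

```r
report <- run_trial(trial_config(seed = 7))
report
#> Trial report
#>   funnel: screened=175, symptom_eligible=156, eligible=134, randomized=134, dosed=131, analyzed=131
#>   primary: ACSS5 at TOC, clinical_itt population
#> Risk difference (test - reference): -0.0648
#>   95% CI (newcombe): [-0.2088, 0.0822]
#>   margin -0.10: inconclusive
```

175 women were screened to randomise 134; 131 took at least one dose and
form the clinical ITT population. The test arm's success proportion at test
of cure is 6.5 percentage points below the reference arm's, and the lower
confidence bound (−0.209) falls below the −10 % margin — at 67 patients per
arm this trial is underpowered, so the non-inferiority question stays
inconclusive: exactly the design insight the simulator is for.

`report$success_tables` breaks successes down per threshold and window,
`report$abu_table` stratifies late relapse by asymptomatic-bacteriuria
status, and `report$crosstab` crosses microbiological against clinical
outcome. A thin CLI over the same functions lives in
`inst/cli/acsstrial-cli.R` (verbs `simulate`, `adjudicate`,
`evaluate-rules`, `analyze`, `run`).

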