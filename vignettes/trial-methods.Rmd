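---
title: "Symptom-scored cystitis trials: models, thresholds and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-scored cystitis trials: models, thresholds and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsstrial)
```

## The problem

Trials that compare a non-antibiotic agent with standard antibiotic therapy
for uncomplicated acute cystitis (uAC) in women cannot lean on bacterial
eradication as the primary endpoint: the two treatment classes act by
different mechanisms, and asymptomatic bacteriuria after clinical recovery
may even protect against recurrence. The primary endpoint must therefore be
the clinical outcome, measured with a validated patient-reported instrument,
with microbiology in a supporting role. `acsstrial` implements the full
chain such a trial needs: symptom scoring, enrolment rules, bacteriuria
significance policies, visit-scheduled cure/failure adjudication,
diagnostic-accuracy evaluation of candidate enrolment rules, and a
non-inferiority comparison of success proportions — plus a seeded synthetic
cohort generator so each stage is testable without patient data.

## The instrument and its scores

The Acute Cystitis Symptom Score (ACSS) is an 18-item self-report
questionnaire in two parts (diagnostic Part A, follow-up Part B) with four
domains: six *typical* cystitis symptoms, four *differential* items, three
*quality-of-life* items — each on a 4-point ordinal scale, 0 (absent) to 3
(severe) — and five dichotomous *additional* condition flags. Part B adds a
*Dynamics* item on the overall course. Domain scores are plain sums of the
ordinal severities.

The typical domain (frequency, urgency, dysuria, suprapubic pain, sense of
incomplete bladder emptying, visible blood in urine — in this fixed item
order everywhere in the package) admits four nested sub-scores: the EMA
guideline's three symptoms, the FDA guideline's four, the first five ACSS
symptoms, and all six. `variant_score()` is monotone in this nesting, which
several tests exploit as an invariant.

Two encodings were genuinely open:

* **Dynamics scale.** The instrument's response scale for the Dynamics item
  is not fixed by the sources available to the package; we encode it as an
  ordinal 0–4 (0 = fully recovered … 4 = worse) and isolate the choice in
  one place (`acss_response`) so a different anchoring only touches the
  translation layer.
* **Missing items.** No imputation: all cure/eligibility thresholds are
  defined on complete summary scores, so a response with a missing scored
  item is invalid for scoring. `validate_response()` returns the complete
  violation list as a value rather than raising, so batch imports can report
  every defect at once.

## Enrolment rules

The recommended inclusion rule for a comparative uAC trial combines three
criteria, all with inclusive boundaries:

* summary score of the six typical symptoms ≥ 6,
* at least one symptom more than mild (severity ≥ 2),
* documented pyuria: ≥ 10 WBC/mm³ in mid-stream urine.

Each component of `diagnostic_rule()` is switchable so that competing rules
(EMA three-symptom, FDA four-symptom, score-only, pyuria-only) can be swept
over the same cohort with `rule_sweep()`. Two deliberately conservative
defaults: mild visible hematuria does *not* satisfy the more-than-mild
requirement (it discriminates cases from controls even when mild, but that
is evidence, not a stated criterion — the `mild_blood_qualifies` flag
enables it), and differential-domain items do not block enrolment (no
published cut-off; `exclude_differential` enables a ≥ 2 exclusion).

## Bacteriuria significance

Four policies resolve an isolate to significant / not significant:
the classical species-blind 10⁵ CFU/mL rule (`general_1e5`), the 10² CFU/mL
rule proposed as the best diagnostic criterion for symptomatic women
(`stamm_1e2`), a 10¹/10² CFU/mL rule taking the most sensitive end of the
reported range for *E. coli* and *S. saprophyticus* (`hooton_low`), and the
species-aware rule (`s3_species_aware`, the package default): *E. coli*
significant at any count in a symptomatic woman, enterococci and group B
streptococci never significant, other recognised uropathogens at a
configurable threshold (default 10³ CFU/mL — configuration, not a published
constant, since no list or cut-off is enumerated for them). Species
matching is by label; no strain typing is attempted, so "persistence"
means re-isolation of the same species label.

## Visit schedule and adjudication

Follow-up windows in days since treatment start: early effect 2–4, end of
treatment 5–9, test of cure (TOC) 5–7 days *after the end of treatment*,
late follow-up 24–33. A day in overlapping windows (possible for very short
treatments) takes the later-stage label, because later windows are
analytically primary. Days outside every window are `"unscheduled"` and
excluded rather than imputed.

Clinical cure at a visit, under the favoured five-symptom threshold: summary
score ≤ 5, no symptom more than mild, and no visible blood. Its complement
is exactly the failure rule (score ≥ 6 *or* any symptom ≥ 2); the test suite
proves the partition by enumerating all 4⁵ severity vectors, and
`cure_score_floor()` recovers the failure cuts 6 / 5 / 4 for the
five-/four-/three-symptom variants by the same enumeration. Because cure
caps every item at mild, the summary-score clause is mathematically
redundant given the per-item cap — also verified exhaustively — so the two
stated criteria cannot disagree.

Two hedged readings are kept apart deliberately: visible blood of any
severity blocks the "cure" status *and* raises a separate `hematuria_flag`,
since persistent hematuria raises the suspicion of a non-infectious source
needing differential work-up, whatever the adjudicated status. Rescue
antibiotic therapy is always failure, regardless of symptoms. The
quality-of-life-augmented threshold encodes "QoL criteria added" as all
three QoL items ≤ 1 (the published account says only that adding QoL lowers
success rates; the cap is a config value), and the Dynamics-only threshold
counts only the top recovery level as success — included for comparability,
not recommended, as an overall self-assessment alone is not sensitive
enough.

## Diagnostic accuracy

`metric_report()` computes the standard battery from a 2×2 table.
Choices that the sources leave open:

* **AUC of a binary rule** is the one-point trapezoidal ROC area,
  (sensitivity + specificity)/2; for score-valued rules `score_auc()` uses
  the rank (Mann–Whitney) formulation with ties counted half, which equals
  the trapezoidal area under the empirical ROC across all cut-offs and is
  checked against an all-pairs brute-force oracle to 10⁻¹².
* **"Correlation with positive outcome"** is implemented as the phi
  coefficient — for binary rule × binary reference, the Pearson correlation
  *is* phi — since no estimator is named.
* **Zero cells**: ratio metrics (LR±, DOR) get the Haldane 0.5 correction
  by default, with the uncorrected value reported as undefined alongside,
  preserving both conventions.
* **Intervals**: Wilson score for proportion metrics (exact boundary
  behaviour at 0 and 1), log-scale normal for LR and DOR.

## Non-inferiority analysis

The primary analysis is the risk difference in clinical success (test −
reference) at TOC in the clinical ITT population, against a −10 percentage
point margin. The default interval is the Newcombe hybrid Wilson score
interval, which stays inside [−1, 1] and behaves at boundary proportions;
Wald is kept for textbook comparability and the Miettinen–Nurminen
constrained-score interval (with the N/(N−1) variance inflation, bounds by
root-finding on the score statistic) as the `score` method. Non-inferiority
requires the lower bound *strictly* above the margin — the conservative
reading of "margin of −10%". Only one threshold is primary (pre-specified);
the other thresholds are descriptive, so no multiplicity adjustment is
applied. The ITT / clinical ITT / microbiological ITT populations are
nested filters; making the micro-ITT exclusion explicit matters because the
species-blind 10⁵ rule can exclude about half of genuinely symptomatic
patients.

## What the generator emulates — and what it does not

`generate_diagnostic_cohort()` emulates a case/control accuracy study
(preset `study2019`: 285 cases, 232 controls; physician diagnosis as the
reference standard). Defaults were fixed once, at design time:

* Per-item severity distributions for cases and controls were calibrated by
  Monte Carlo so the six-symptom score ≥ 6 + more-than-mild rule operates
  near sensitivity 0.85 / specificity 0.88 — the published range for
  symptom-only rules on the development data.
* WBC densities are status-specific log-normals calibrated so pyuria alone
  (≥ 10 WBC/mm³) operates near sensitivity 0.85 / specificity 0.72, its
  published operating point. Colony counts are log-uniform over 10¹–10⁸
  CFU/mL with a mixed species palette dominated by *E. coli*.
* Severities are drawn independently across items: no correlation structure
  is published. An optional shared latent-severity blend (`latent_mixing`)
  induces positive item correlation for stress-testing rules; it is off by
  default.

`generate_trial()` emulates a two-arm outcome study (preset `outcome2023`:
134 patients, 67 per arm): screening draws presenting patients until the
target number is eligible (yielding an explicit funnel), permuted-block 1:1
randomisation (block size 4 — a convention, not a published value), a
latent resolved/unresolved state per window from per-arm
`visit_success_prob`, observed Part B severities drawn from the state's
distribution, rescue therapy forcing the unresolved state from the rescue
day on, asymptomatic bacteriuria among TOC resolvers, and relapse at late
follow-up. The default per-arm success probabilities are plausible
mid-range values chosen once (reference arm slightly ahead of the test arm,
both rising from the early visit to TOC); none is presented as a published
result, because the published outcome tables exist only as figure images.

The late-follow-up state has two modes by design. With a relapse matrix
(the `outcome2023` preset: relapse 5% with ABU, 15% without, either arm —
encoding the hypothesis that ABU protects against recurrence), TOC
resolvers relapse per ABU status and arm, so the late window reflects the
relapse mechanism rather than an independent draw. With
`relapse_prob = NULL`, every window — including late follow-up — is an
independent Bernoulli draw from `visit_success_prob`; this is the
configuration `recovery_harness()` is meant for, because then the
adjudicated success proportion is an unbiased binomial estimate of the
latent probability at every window and parameter recovery is a clean
sampling check.

What passing tests on this generator do **not** show about real data:
real symptom items are correlated, severity trajectories are serially
dependent within patients (the generator draws windows independently),
missingness is ignorable here but not in clinics, and the case/control
separation is as clean as its calibrated operating points — a cohort with
atypical presentations would degrade every rule together. The generator
validates the *machinery*, not the clinical performance claims.

## Numerical and testing choices

* All thresholds are inclusive (≥), matching their definitions; the single
  strict inequality in the package is the non-inferiority margin.
* Probability-vector and distribution inputs are validated to sum to 1
  within 10⁻⁹.
* Enumeration tests run the full 4⁵ and 4⁶ grids (1,024 / 4,096 vectors);
  they are exact, not sampled.
* Monte-Carlo problem sizes used by the test suite, chosen to keep each
  estimate's error far below the tested tolerance: interval coverage uses
  2,000 simulated trials at 200 patients/arm and true success 0.8 (coverage
  asserted within the 93–97% band); parameter recovery uses 500 replicates
  of 100-patient trials with degenerate resolved/unresolved severity
  distributions (estimates asserted within 3 Monte-Carlo standard errors);
  marginal calibration uses a 10,000-subject cohort with per-item χ²
  goodness-of-fit at α = 0.01 (a 1% false-alarm rate per item is accepted
  and pinned by a fixed seed).
* Generator determinism is tested down to byte-identical written CSV files.

## Known limitations

* Species matching is label-based; mixed flora / contamination handling
  (e.g. ≥ 3 species) is not modelled, as no rule is published.
* The hematuria flag is per visit; "persistent" hematuria across
  consecutive visits is left to the analyst (the adjudication export keeps
  the flag per visit precisely so this can be done downstream).
* No safety/adverse-event coding, no interim analyses, no sample-size
  formulae beyond what simulation with the generator provides.
* The −10% margin is applied at TOC only; whether it should also bind at
  late follow-up is a protocol decision the package leaves to configuration.
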