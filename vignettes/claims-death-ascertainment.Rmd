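---
title: "Ascertaining death from monthly claims: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascertaining death from monthly claims: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deathproxy)
```

## The problem

Monthly administrative claims record, for each patient and calendar month,
the care billed, its setting (inpatient/outpatient), ICD-10 diagnoses, and
a discharge/disease status taking one of four values: `death`, `cure`,
`termination`, `others`.  When the insurer's enrollment file — which holds
the actual death date — is unavailable to researchers, death must be
inferred from the claims.  This package implements a family of such
definitions, validates them against an enrollment gold standard when one
is available, and quantifies the consequences of using them as a study
outcome when one is not.

Everything is computed at calendar-month resolution (`ym` objects), the
native granularity of the claims system; day-level inputs are truncated to
the month with a message.  Each patient's observation runs from the
enrollment month to the earlier of the disenrollment month and the
administrative study end.

## The definition family

The status-based arm starts from the **index claim**, the earliest claim
in either setting whose status is `death`.  The paradox the family must
handle is the **zombie claim**: a claim without death status issued in a
month *after* the index claim.  Zombies within 1–2 months are typically
reimbursement lag for services consumed before death; gaps of 3 or more
months almost certainly mean the patient is alive and the index claim was
miscoded.  Definitions 1.1/1.2/1.3 accept all index claims, reject any
zombie, and reject only long-term zombies, respectively.

The severity arm needs no death-status claim.  Definition 2.1 flags
patients whose **last inpatient claim** scores 6 or more on the Charlson
comorbidity index; 2.2 additionally requires a **blank period** — at
least 6 claim-free months between the patient's last claim of any kind
and the study end; 2.3 additionally requires a CCI ≥ 6 claim during the
12 months preceding the last admission (a sustained severe illness, not a
one-off coding).  Definitions 3.k are the unions 1.3 ∪ 2.k, and 3.3 is
the usual recommendation: it adds out-of-claim deaths captured by the
severity arm while the blank-period and lookback conditions protect its
positive predictive value.

The assigned death month is the index month for 1.x, the last-admission
month for 2.x, and the earlier of the two for 3.x.  For the severity arm
this is a convention: the claims do not say when between admission and the
end of the blank period the patient died, and we prefer the observable
anchor over an extrapolated one.

## Decisions the definitions leave open

The definition table does not pin down every corner case.  The package's
choices, all deterministic:

* **Several death-status claims.** The earliest is *the* index claim;
  later death-status claims are neither zombies nor new indices.  Earliest
  is conservative (it maximizes the window in which zombies can be seen)
  and order-independent.
* **Zombie horizon.** A gap is long-term when it exceeds
  `zombie_short_max_months` (default 2), i.e. 3 months or more, matching
  the short/long taxonomy above.  Zombies are scanned among *all* loaded
  claims, including those after the disenrollment month: a death-month
  disenrollment is followed by exactly the reimbursement-lag claims the
  taxonomy is about, so hiding them would collapse 1.2 into 1.1.  Claims
  after the administrative study end are dropped at load, with a warning.
* **Blank-period anchor.** The blank period runs from the patient's last
  claim of any kind (not the index claim) to the study end month: zero
  months if a claim falls in the final month.  It is measured against the
  study end rather than the observation end, so a death-month
  disenrollment naturally produces a long blank.
* **Lookback boundary.** The window before an anchor month `a` is
  `[a − 12, a − 1]`: the boundary month is included, the anchor month
  itself is not ("preceding" excludes the admission being scored).
  Lookback claims are scored claim by claim, in either setting.
* **Same-month pooling.** Inpatient claims in the same month are one
  fragmented admission: their diagnoses are pooled before scoring the
  "last inpatient claim".  Pooling happens only there.

## Charlson scoring

The package ships an ICD-10 prefix table for the 17 Charlson categories
with the original weights (1, 2, 3, 6), in the style of the published
administrative-data adaptations, as a versioned CSV under `inst/extdata`
(`cci_map()` loads it; any user table with columns
`category,weight,prefix` can replace it).  Matching is dot- and
case-insensitive and the *longest* matching prefix wins, so `E11.2`
resolves to complicated diabetes (weight 2) while `E11.9` stays
uncomplicated (weight 1).  Hierarchy pairs — diabetes without/with
complications, mild/moderate-severe liver disease, malignancy/metastatic
tumour — count only the severe member when both appear, the standard
Charlson practice; `apply_hierarchy = FALSE` disables it, since published
uses of the severity criterion are not always explicit about suppression.
Unmapped codes contribute nothing.  With the original weights, a single
code reaches the ≥ 6 criterion only through metastatic solid tumour or
AIDS/HIV; the package's tests assert this boundary.

## Validation conventions

Agreement with the gold standard is patient-level: a true positive is a
definition-positive patient whose enrollment record shows a death month,
with no attempt to match the assigned month to the death month.
Percentages are rounded half away from zero to one decimal — specificity
to two, since usable definitions live above 99.9% and one decimal would
erase their differences.  Confidence intervals are exact
(Clopper–Pearson); Wilson intervals are available behind
`ci_method = "wilson"`.  A zero denominator yields a flagged `NA`, never a
silent 0.

One conservative rule deserves a flag of its own: a patient whose
disenrollment month equals the call month but whose disenrollment reason
is *not* death counts as a false positive.  Such patients are plausibly
deaths whose reason field was never amended, so
`reclassify_ambiguous_disenrollment = TRUE` re-scores them as true
positives, quantifying how much the conservative reading understates
sensitivity.

Subgroup validation evaluates each stratum with its own denominators.
Age is taken at the observation end (the enrollment file gives a birth
year, not a birth date, so any reference point is a convention);
"hospitalized in the preceding year" means an inpatient claim within the
12 months before the observation end; the setting of the last claim is
inpatient if any claim in the last claim month is inpatient.

## The synthetic generator

`simulate_cohort()` generates cohorts whose structure the definitions
exploit, with a per-patient truth table so every test has an oracle.  Its
defaults are the study conditions of the validation setting the package
models: ~195k working-age beneficiaries (60% male; age bands 58/31/11%;
66% employees) observed January 2005–August 2009, a background monthly
outpatient claim probability of 0.15 (inpatient 0.005) with 13% of
beneficiaries never generating claims, 40% enrolled at the window start
and the rest uniformly during it, a small monthly non-death disenrollment
hazard (0.003), and a true-death probability of ~0.36%.  The mechanism
probabilities are calibrated to the validation study's observed cell
magnitudes: a true death produces a death-status claim with probability
0.581 (the target sensitivity of definition 1.1), a recorded death trails
short zombies with probability 9/395, a living patient carries a miscoded
death claim with probability 4/194513, a death is recorded only as a
reasonless disenrollment with probability 14/694, a decedent's final
admission is Charlson-severe with probability 215/680 (with a severe
lookback claim in 80% of those), and a living patient has a severe
admission with probability 75/194513.

What it deliberately does not emulate: realistic ICD-10 code frequencies
beyond what Charlson scoring needs (background claims draw from a small
benign pool), seasonality, costs, or correlated utilisation.  Tests
passing on these cohorts therefore certify the *logic* of the definitions
and the estimators, not their real-world operating characteristics.

`mechanism_cohort()` is the deterministic counterpart: it realizes a
prescribed number of patients of every mechanism class (clean death
claims, short/long zombies, reasonless disenrollments, nested
severe-admission patterns, age-band mixes), which makes the complete
validation table reproducible exactly, cell by cell, at any scale of
true-negative filler.

## The bias simulator

`simulate_two_group()` draws exponential event times at group-specific
hazards (reference hazard `baseline_rate`/100/12 per month, exposed
scaled by the true HR), censors administratively at the follow-up
horizon, and thins events by each group's ascertainment sensitivity
(specificity defaults to 1, matching definitions whose specificity
exceeds 99.9%; a flipped survivor becomes an event at the censoring
time).  `estimate_hazard_ratio()` fits a Cox model adjusted for age and
sex — generated independent of group, so the adjustment is pure noise by
default; a confounded design can be built by the user on top of the
returned data.  In the rare-outcome regime the observed hazard ratio is
approximately `HR × s_exposed / s_reference`
(`expected_observed_hr()`), the closed form every Monte-Carlo summary is
checked against.

`run_bias_experiment()` reports mean log-HR bias, model-based and
empirical precision (inverse variance of the log HR — the model-based
version is what applied papers quote), and CI coverage of the thinning
prediction.  Replicates in which a group has no observed events are
counted and excluded from the summaries.  Two presets encode example
study structures: `"study1"`, a small two-arm comparison with nearly
complete ascertainment in both arms, and `"study2"`, a strongly
differential comparison (sensitivities 7/23 vs 27/30 at true HR 0.27) in
which the claims-based HR collapses toward the thinning prediction and
loses about half its precision.

## Problem sizes and tolerances

The test suite works at sizes chosen to make binomial and Monte-Carlo
error bars meaningful: oracle equivalence of the vectorised ascertainment
against a naive per-patient re-derivation on 1,000 fuzzed histories plus
300-history unit fixtures; generator recovery of the recording rate on a
20,000-death cohort with a 3-standard-deviation binomial band; bias
experiments at 500 replicates with a 3-Monte-Carlo-standard-error band
(group sizes 12,000/6,000 at a 2-per-100-person-year baseline for the
differential case, so the rare-outcome approximation holds while event
counts keep per-replicate noise modest).  The acceptance script rebuilds
the full-scale engineered cohort (195,193 beneficiaries) because
specificity only becomes 99.99% at the real denominator.

## Limitations

The package handles monthly claims with a four-valued status field; it
does not parse native receipt formats, assign causes of death, or date
deaths below month resolution.  The bundled Charlson map is a
reconstruction of the published ICD-10 adaptation style, not a clinical
authority — studies with their own mapping should supply it as a file.
Validation requires an enrollment gold standard, which is exactly what
real target databases lack; the point of the validation machinery is to
transport validity estimates from a database that has one.  The bias
simulator covers fixed two-group exposures with exponential baseline
hazards; time-varying exposures and competing risks are out of scope.
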