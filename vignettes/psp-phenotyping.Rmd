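---
title: "Phenotyping progressive supranuclear palsy with psprules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping progressive supranuclear palsy with psprules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psprules)
```

## The clinical model

Progressive supranuclear palsy (PSP) is a 4-repeat tauopathy whose
clinical diagnosis is operationalized by the MDS-PSP criteria around four
core functional domains: ocular motor dysfunction (O), postural
instability (P), akinesia (A) and cognitive dysfunction (C). Each domain
contributes three binary features stratified by the level of diagnostic
certainty they carry (stratum 1 the highest, 3 the lowest); four clinical
clues (CC1–CC4) act as supportive features. `psp_features()` lists the
vocabulary. Combinations of present features assign one of eight
phenotypes — Richardson's syndrome (PSP-RS) and seven variants — at a
certainty level of *probable*, *possible* or *suggestive of*, a total
order the whole package respects (`certainty_levels()`).

The rule set is data, not code: `inst/extdata/mds_psp_rules.tsv` holds one
row per (phenotype, certainty) pair with a positive boolean formula in
disjunctive normal form over feature codes. All 16 rows are monotone (no
negated literal anywhere), which has two useful consequences: adding a
feature can never lower any phenotype's allocated certainty, and each
formula's minimal satisfying assignments are exactly its conjuncts
(`minimal_profiles_for_row()`), giving a complete, enumerable fixture set.

```{r rules}
psp_rules()
```

### Matching semantics

Matching is **literal**: the possible PSP-RS row names O2, and a patient
with O1 but not O2 does not satisfy it, exactly as the combination table
prints it. The engine offers an optional *stratum subsumption* mode
(`subsume_strata = TRUE` in `evaluate_allocations()`) in which a
higher-certainty feature of the same domain also satisfies lower-stratum
slots; it exists for sensitivity analyses, defaults to off, and every
shipped check runs with it off.

Each phenotype is reported once, at the highest satisfied certainty, and
its `satisfied_by` set is the union of present features across all
satisfied conjuncts of the winning row — the full set of features that
drive the allocation, which is also what anchors the phenotype in time
(below).

One documented discrepancy: the criteria's supplementary guidance states
that clinical clues determine neither certainty nor phenotype, yet the
combination table's suggestive-of PSP-P row lists CC1–CC4 as qualifying
partners of A2/A3. The table is taken as authoritative, so the clues
participate in that one row and nowhere else.

## Composite features and the temporal gate

Four derivations turn raw sub-observations into core features:

* **C2 (frontal presentation)** — at least 3 of 5 items (apathy,
  bradyphrenia, dysexecutive syndrome, reduced phonemic fluency,
  impulsivity/disinhibition/perseveration). Total function; derived both
  ways (fewer than 3 items recorded as present derives C2 absent).
* **C3 (corticobasal syndrome)** — at least one cortical sign (orobuccal
  or limb apraxia, cortical sensory deficit, alien limb) *and* one
  movement-disorder sign (rigidity, akinesia, myoclonus). Also total.
* **A2/A3 (levodopa resistance)** — improvement of the MDS-UPDRS motor
  score `(pre − post) / pre ≤ 0.30` under a qualifying regimen: a
  challenge dose ≥ 200 mg, or ≥ 1000 mg daily for one month, encoded as
  ≥ 30 days (the criteria give no day count). The pre-score denominator
  is the conventional percent-improvement reading; the criteria print no
  formula. Worsening (negative improvement) counts as resistant.
  Resistance is *positive evidence only*: a resistant result fills A2,
  a responsive one fills A3, and neither forces the other absent, because
  each feature also embeds phenomenology (axial-predominant rigidity,
  tremor/asymmetry) the challenge does not measure. Without a qualifying
  regimen, or with a zero pre-score, the result is not assessable (`NA`).
* **P2/P3 (pull test)** — a fall if not caught maps to P2; more than two
  steps backward with unaided recovery maps to P3 (two steps exactly does
  not qualify); the observation's month is passed through as the
  feature's onset. Like the levodopa challenge, only positive outcomes
  fill features.

When a record carries both raw observations and an explicit 0/1 flag for
a derived code and they disagree, the explicit flag wins and a warning is
raised — the smartsheet-style 1/0 entry is the primary input.

**Temporal gate.** The criteria require P1, P2, P3 and A1 within the
first three years of disease. `apply_temporal_gate()` removes any of
those four features whose recorded onset exceeds the window
(default 36 months, boundary inclusive: onset = 36 is retained, a
deliberate reading since the criteria say "within 3 years" without
boundary semantics). Features without a recorded onset are trusted as
temporally valid — the gate is opt-in via onset data, because plain 1/0
profiles carry no time information. Gating acts on recorded onset only;
whether a feature *first documented* late was historically present
earlier is an assessment question the package does not second-guess. The
gate is idempotent and can only remove features. Two smaller vocabulary
choices in the same spirit: macro square wave jerks and eyelid opening
apraxia share the single O3 flag, and nfaPPA and progressive apraxia of
speech share C1, since the rules never distinguish within either pair.

## MAX resolution

A visit often satisfies several rows at once. `resolve_max()` filters the
allocation set lexicographically:

1. **Diagnostic certainty** — keep only allocations at the maximum level.
2. **Temporal order** — among ties, keep the earliest phenotype onset,
   where a phenotype's onset is the earliest recorded onset among its
   `satisfied_by` features. If any contributing feature lacks an onset
   the phenotype's onset is unknown; unknown onsets rank after every
   known onset and tie with each other, so absence of evidence never
   promotes a phenotype.
3. **Hierarchy** — PSP-RS prevails over any variant.
4. Any residual variant-vs-variant tie falls to a fixed order (PSP-PGF,
   PSP-P, PSP-F, PSP-SL, PSP-CBS, PSP-OM, PSP-PI), shipped as
   configuration (`inst/extdata/max_tie_break.tsv`); the criteria print
   no order among variants, so this is a package convention chosen to
   make resolution total and deterministic.

The criteria's fourth clause ("MAX rule 1 prevailing over MAX 2 and 3")
is read as a statement of precedence among the first three steps rather
than an extra tie-breaker, hence the strict 1→2→3 application above.
Exactly one allocation survives whenever any rule fired; every
extinguished allocation is labelled with the rule that removed it, and
the trace lists each applied step, so a report doubles as a teaching
walk-through.

```{r max}
p <- psp_profile(c("O1", "P1", "A1"), onset = c(O1 = 4, P1 = 6, A1 = 3))
psp_diagnose(p)
```

**Probable 4R-tauopathy.** The joint PSP/CBD trial-recruitment category
is a lookup over the final (phenotype, certainty) pair. The criteria
papers this package operationalizes do not print the membership table,
so it ships as explicit, overridable configuration
(`inst/extdata/tau_map_4r.tsv`), with a default imported from the MDS
criteria publication (Höglinger et al. 2017, Mov Disord 32:853–864):
probable certainty at any phenotype, plus possible PSP-CBS, qualify.

## Synthetic data

No patient-level dataset exists or is needed. Two generators cover all
testing:

* `enumerate_profiles()` yields the full boolean cube over the 16
  features — 65,536 profiles, small enough that every engine property is
  checked *exhaustively* rather than by sampling: agreement with an
  independently hand-transcribed evaluator, per-phenotype allocation
  uniqueness, monotonicity under feature addition, the single-survivor
  and certainty-supremacy invariants of MAX resolution.
* `sample_cohort()` draws records with independent Bernoulli feature
  presence at configurable marginal prevalences and optional uniform
  onset times. The defaults (`psp_default_prevalence()`) are chosen once
  to resemble a moderately advanced PSP clinic population — vertical gaze
  involvement and falls common (0.55, 0.60), gait freezing and
  speech/language presentations rare (0.10, 0.08), clues at a 0.20
  background — values a movement-disorders reader would recognize as
  plausible cohort frequencies rather than estimates of any specific
  series.

The generator deliberately has **no disease-progression model**: features
are independent, prevalences are marginal, and onsets are uniform. Real
PSP features co-occur and accrue over time, so passing tests demonstrate
the correctness of the rule algebra and the I/O contracts on arbitrary
profiles — not calibration of phenotype frequencies against any clinical
population. Cohort-level counts from simulated data are properties of the
chosen prevalences, nothing more.

## Numerical and testing choices

* The engine is pure boolean algebra; the only numeric comparisons are
  the levodopa ratio (≤ 0.30, inclusive), the pull-test step count
  (> 2, strict) and the gate boundary (≤ 36 months, inclusive), each
  fixed as documented above.
* Ties inside a rule row (several conjuncts satisfied) do not need
  breaking: `satisfied_by` is their union.
* Degenerate inputs are explicit outcomes, not errors: an empty profile
  or an empty rule table yields "no PSP allocation" with an empty trace;
  a non-assessable levodopa challenge derives nothing.
* Problem sizes used by the shipped checks: the full 65,536-profile cube
  for all exhaustive properties (a few seconds of compute), 10,000
  records for the prevalence-recovery check (within three binomial
  standard errors), 1,000 records for the end-to-end acceptance cohort,
  and smaller seeded cohorts for I/O round trips.
* Determinism: identical inputs always produce identical reports;
  `sample_cohort()` is seed-stable and restores the caller's RNG state.

## Limitations

* The package implements the combination table and MAX resolution, not
  the criteria's mandatory inclusion/exclusion criteria (sporadic
  occurrence, age at onset, gradual progression) or the prodromal
  "suggestive of PSP" framework beyond the table's rows; a classification
  therefore presumes the patient is already an appropriate candidate for
  the criteria.
* Imaging findings play no role, mirroring their lack of a specific role
  in phenotype attribution.
* Visits are classified independently; longitudinal synthesis across a
  patient's visits is reporting, not re-diagnosis.
* Clinical sign recognition (how to elicit vertical supranuclear gaze
  palsy, saccade testing technique) is outside scope: inputs are binary
  assertions made by the examining clinician.
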