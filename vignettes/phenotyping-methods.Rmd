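---
title: "Rule-based sarcoidosis phenotyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based sarcoidosis phenotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcphen)
```

## The procedure and its assumptions

`sarcphen` classifies patients from structured EMR extracts with a fixed,
fully deterministic rule set. The pipeline assumes that everything it
needs has already been abstracted into structured fields: feature flags
for the supportive clinical/radiological findings, biopsy records with a
site and a histopathology result, chest-imaging findings, PFT values
with their lower limits of normal (LLN), and treatment/course history.
The package performs no text mining; if a finding lives only in a
narrative note, the pipeline cannot see it.

The stages are:

1. **ICD capture** (`match_icd_codes`). A claim qualifies when its code
   is exactly `135`, begins `135.`, or begins `D86`. The ICD-9 rule is
   intentionally *not* a plain prefix match: other coding systems contain
   codes that begin with the digits 135, and capturing them would be a
   silent false-positive source. The code system of the earliest
   qualifying claim is reported; undated claims rank earliest, and ties
   prefer ICD-9, the only ordering consistent with extracts whose
   observation window predates ICD-10 adoption.
2. **Index of suspicion** (`index_of_suspicion`). *High* iff at least one
   of the 23 feature flags is present. This is a pure disjunction — no
   weighting, no counting — which gives it two properties the test suite
   verifies directly: monotonicity (adding a feature can never lower the
   index) and biopsy-blindness (the biopsy list is never consulted, so
   probable cases without histopathology are reachable).
3. **Case grouping** (`classify_case`). High + any biopsy showing
   nonnecrotizing granulomas (primary or secondary provenance) →
   `confirmed_biopsy`; high otherwise → `probable_no_biopsy`; low →
   `unlikely`. Histopathology without supportive features does *not*
   make a case: granulomatous inflammation alone is nonspecific, and the
   adjudication standard here is the feature-based index.
4. **Organ involvement** (`assess_organ_involvement`). Per organ, a
   granulomatous biopsy at a qualifying site *or* any of the organ's
   feature flags (see `organ_criteria()`). The multi-organ phenotype is
   involvement of ≥ 3 organs.
5. **Scadding stage** (`scadding_stage`) from imaging findings, and
   **PFT pattern** (`pft_pattern`) from measured values vs their own LLN.
6. **Phenotype groups** (`assign_phenotype_groups`): nine non-exclusive
   clinical groups (multi-organ; stage I untreated; stage II–III
   treated/untreated; stage IV treated/untreated; acute; remitting;
   cardiac treated).

## Parameters that matter

* **Confidence level** (`level`, default 0.95): all intervals are exact
  Clopper–Pearson, computed in the beta-quantile form. At `x = n` the
  lower bound has the closed form `(α/2)^(1/n)`.
* **PFT thresholds**: there are no package-level cutoffs; each value is
  compared against the LLN shipped with the record (fractions for
  FEV1/FVC, liters for TLC/FVC, percent predicted for DLCO). When TLC is
  absent, FVC below its LLN stands in for restriction — the standard
  spirometry-only surrogate.
* **Fisher mode** (`mode`, default `"exact"`): exact enumeration is
  limited to tables with total ≤ 500 and at most 6×6; beyond that the
  seeded Monte-Carlo mode must be requested explicitly so that results
  remain reproducible.
* **Simulator rates** (`cohort_spec`): per-feature prevalences (default
  0.05 each), biopsy-given-high 0.9, granuloma-given-biopsy 0.95, ICD-9
  fraction 0.68, male fraction 0.9 — values in the range a veterans-care
  sarcoidosis cohort would show. `prevalence_for_high_rate()` converts a
  target high-index probability into a common per-feature prevalence via
  `1 − (1 − p)^23`.

## Numerical and tie-break choices

* **Stage IV dominance**: fibrotic end-stage disease wins over
  coexisting nodal or parenchymal findings, matching the conventional
  reading of the staging ladder as severity-ordered at the top.
* **Isolated low DLCO**: a normal-mechanics PFT with low diffusing
  capacity is classified `normal` for the four-level pattern; the
  boolean `pft_low_dlco()` carries the information separately, because
  the four-level pattern has no DLCO-only category and silently
  promoting it to "restrictive" would distort the pattern marginals.
* **Liver/spleen criteria**: laboratory-only liver-enzyme abnormality is
  *not* an involvement trigger; the organ requires the exam flag
  (hepatosplenomegaly) or the imaging flag (lesions). A lab-only
  criterion would create organ involvement in patients carrying none of the
  feature flags at all, which the rest of the rule set never does. This is a
  documented simplification.
* **Merged "or" features**: vocabulary items listed as alternatives
  (e.g. optic neuritis / scleritis / uveitis / retinitis) are one flag,
  because every downstream rule only tests presence-of-any.
* **Group 8 ("remitting, untreated")**: driven by the remitting flag AND
  the absence of treatment within 3 months of review. "Untreated" is
  genuinely ambiguous for a remitting patient — someone treated years ago
  may have remitted since — so the package uses the recent-treatment
  reading and documents it here.
* **Groups 3/5 "treated"**: implemented as *ever treated* (a superset of
  treated-within-3-months), the literal reading of the group definition.
* **Fisher two-sided rule**: sum of probabilities of all
  margin-preserving tables no more probable than the observed one, with
  the conventional `1 + 1e-7` relative tie tolerance (the test oracle
  enumerates all candidate tables independently).
* **Chi-square**: no continuity correction by default; `yates = TRUE` is
  available for 2×2 tables.
* **Report formatting**: percentages are printed to one decimal;
  machine-readable JSON reports round to four decimals.

## The synthetic fixture cohort

No patient-level chart-review data can ship with a package, so the
validation cohort is synthetic and *constructed*, not sampled:
`build_fixture_cohort()` lays out 200 records (100 per site) whose raw
features — and only features; no derived label is ever stored — yield,
through the real pipeline, the 47 marginal counts recorded in
`fixture_manifest()`: 158 high-index (108 ICD-9-first / 50 ICD-10-first,
142 men, 85 African American), 142 biopsy-confirmed vs 16 probable, 42
feature-free unlikely patients, 143 pulmonary and 60 multi-organ cases,
the full Scadding (27/26/47/21/22/15) and PFT-pattern (28/36/25/40/29)
distributions, the phenotype-group counts, and subgroup age summaries
(65.5 ± 10.8 vs 69.3 ± 10.3 years, via a symmetric two-point age
construction that hits mean and SD exactly at one decimal).

Two design points deserve emphasis:

* **The joint assignment is one concrete solution.** Marginals do not
  determine the joint distribution; the fixture fixes one layout chosen
  for internal consistency. In particular, all 15 non-pulmonary cases
  carry neither an imaging report nor a PFT, which is the unique
  arrangement under which the stage distribution, the pattern
  distribution, and the "129 of 143 pulmonary cases have a PFT" count
  can hold simultaneously. Only the manifest's marginals are
  contractual; nothing downstream may rely on which particular patient
  is, say, stage IV and remitting.
* **Groups 4 and 6 are forced, not free.** Under the group definitions,
  groups 3+4 partition the stage II–III cases by treatment and groups
  5+6 partition stage IV. With 68 stage II–III and 22 stage IV cases and
  the treated counts fixed at 45 and 17, the untreated groups are
  mechanically 23 and 5. A fixture cannot satisfy arbitrary group-4/6
  targets independently of the stage and treatment marginals, and the
  manifest records the forced values.

What the fixture does *not* emulate: longitudinal claim structure (most
patients carry a single qualifying claim), free-text provenance,
correlated feature noise, missing-not-at-random documentation gaps, or
inter-site differences (the 100/100 site split has no classification
consequence). Passing the fixture checks therefore demonstrates that the
rule engine and the statistics are implemented correctly at cohort
scale — not that the rule set would achieve the same accuracy on any
particular live EMR.

## The stochastic simulator

`simulate_cohort()` draws records independently: feature flags are
independent Bernoulli draws at the configured prevalences, biopsy
presence and result follow the conditional rates, and imaging/PFT values
are generated coherently with the drawn flags (so re-deriving
classifications from raw fields reproduces the intended structure). The
independence assumptions are deliberate simplifications — real features
co-occur (a stage II film implies lymphadenopathy and often infiltrates)
— which makes the simulator suitable for calibration and robustness
studies of the *rule engine*, not for realistic epidemiological
simulation. Determinism: the same `cohort_spec` and seed give a
byte-identical cohort file.

## Problem sizes used by the test suite

The property-style tests run the rule engine over 1,000 generated
records, compare against an independent literal-condition oracle on
mini-cohorts of up to 6 patients, check the exact interval against
brute-force tail inversion for all `x` at `n` up to 50, compare the
Fisher test with a full enumeration oracle on sampled tables with totals
up to 20, simulate interval coverage with 10,000 replicates at `n = 30`,
and recover a configured 0.79 high-index rate at `n = 10,000` within
three binomial standard errors. These sizes were chosen so the whole
suite exercises every rule path and statistical branch while remaining a
sub-minute desk-scale run.

## Known limitations

* The pipeline is exactly as good as the upstream structured abstraction;
  it contains no differential-diagnosis exclusion step, which requires
  clinical judgment over narrative text.
* Specificity and likelihood ratios are not estimable from a case-only
  design, and the API refuses to fabricate them.
* The cardiac criteria treat "cardiomyopathy responsive to treatment" as
  part of the single cardiac-manifestation flag; a treatment-response
  attribute would require longitudinal data the record model does not
  carry.
* Exact Fisher enumeration grows combinatorially; the 6×6 / total-500
  bound is conservative on purpose.
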