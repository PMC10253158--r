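---
title: "Methods: new-user antidiabetic cohorts, trajectories and adherence from dispensing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: new-user antidiabetic cohorts, trajectories and adherence from dispensing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxcohort)
```

`rxcohort` implements a drug-utilization study design for administrative
pharmacy dispensing data, centred on patients who start antidiabetic (AD,
ATC group A10) therapy. This vignette records the package's methodological
choices: the selection rules, the adherence construction, what the
synthetic generator does and does not emulate, and every numerical
convention a reviewer might want pinned down.

## Data model

One row per dispensation: patient identifier, birth date, gender,
dispensation date, 7-character ATC level-5 code, number of packages, and
the total number of Defined Daily Doses (DDD) dispensed. The DDD is the
assumed average maintenance dose per day, so the DDD total *is* the days of
supply; when a source table lacks it, `days_supplied()` falls back to
total dispensed amount divided by the DDD content per unit. Dates carry day
resolution only; all intervals are closed on the left and open on the
right, measured in whole days. A linked death registry carries one death
date per deceased patient.

Input tables are delimited text with a configurable dialect (delimiter,
date format, column map), because administrative extracts never share a
schema. Rows failing validation — malformed ATC code, unparseable date,
unknown gender, non-positive package count, negative DDD — are rejected
individually and logged in a read report; only a missing mandatory column
aborts a read.

## Cohort selection

The design is a new-user (incident-user) cohort over a four-year data
window (default 2018-01-01 to 2021-12-31):

1. **Age** — at least 18 completed years at the reference date
   (2021-12-31).
2. **Wash-out** — no AD dispensation before 1 January of the index year;
   calendar 2018 must be AD-free, which restricts the cohort to patients
   naïve to antidiabetic treatment.
3. **Index event** — first AD dispensation falls in the index year (2019);
   the index date is that dispensation's date and the index drugs are all
   distinct AD codes dispensed that day (same-day multi-drug starts are a
   reported category, not an error).
4. **Chronic-use filter** — at least 2 AD dispensations in each complete
   calendar year after the index year inside the data window (2020 and
   2021). ADs treat a chronic condition; a patient dispensed once and
   never again is not on chronic therapy. We apply the per-year rule to
   the complete post-index calendar years rather than prorating partial
   years, because partial-year proration is not well defined for a
   mid-year index date; the index year itself requires only the index
   dispensation.
5. **Death** — patients in the death registry with a death date on or
   before the study end are excluded.

Exclusion reasons are assigned in this fixed order, first failure wins, and
the ledger satisfies |input patients| = |cohort| + |ledger| by
construction. Follow-up runs from the index date to the patient's last AD
dispensation or the study end, whichever is earlier. We read "last
prescription" as last *antidiabetic* prescription: the study concerns AD
therapy, and a comorbidity prescription years after AD discontinuation
should not extend AD follow-up.

**Metformin refinement.** The adherence/trajectory cohort keeps members
whose sole index drug is plain metformin (A10BA02). Members dispensed a
second distinct AD within 9 days of the index date — window inclusive of
day 0 and day 9 — are set aside as first-line combination-therapy
initiators: a second drug that soon after initiation is a deliberate
combination regimen, not a therapy change. Day 10 is the first day that
counts as intensification. Distinct-AD identity is the full level-5 code;
a fixed-dose combination (A10BD) is one distinct code, with a built-in
component table marking which A10BD products contain metformin.

Members are subgrouped by the number of distinct AD codes dispensed during
follow-up: 1, 2, 3, 4, 5+.

## Comorbidity profiling

The adapted Rx-Risk Index infers treated conditions from dispensed drug
classes alone: one dispensation in a condition's ATC level-2 class set
during the study period flags the condition. The packaged map has 21
conditions in two blocks — diabetes-concordant (cardiovascular disease
including antithrombotics B01, hypertension C02/C03/C09, hyperlipidemia
C10, hyperuricemia M04) and discordant (infections J01–J07, acid-related
disorders A02, and so on). Compact ranges expand lexicographically within
one letter prefix at load time, and no level-2 code may map to two
conditions. AD dispensations (A10) never contribute: the index profiles
the comorbidities *of* diabetes. No dose or duration threshold applies to
a qualifying dispensation, and the window is the whole study period, not
only follow-up.

Reporting tables keep a condition (or, for the level-1 usage table, an
anatomical main group) only when its prevalence reaches 10 % in at least
one subgroup; rows are grouped by concordance and ordered by prevalence in
the monotherapy subgroup.

## First-intensification trajectories

For a metformin monotherapy initiator, let t\* be the date of the first
non-metformin AD dispensation after the combination window. The label is:

- **monotherapy** if no such dispensation exists;
- **add_on** if the drug at t\* is a metformin-containing fixed-dose
  combination, or if at least one plain-metformin dispensation occurs on
  or after t\* — presence-based evidence that the second drug joined
  continuing metformin. The package deliberately imposes no minimum
  overlap duration: dispensing data shows refills, not intake, and any
  overlap threshold would be arbitrary;
- **switch** otherwise (metformin never reappears);
- **switch_then_discontinue** for a switch after which the patient's last
  AD supply runs out at least 90 days before the study end with no further
  dispensation. The 90-day grace period (`discontinuation_gap_days`,
  configurable) is a conventional pharmacoepidemiologic choice; no
  standard definition exists for "discontinued after switching", so the
  package declares one rather than leaving the category undefined.

Only the first change is classified; later additions feed the distinct-AD
count but not the label. Reporting classes map the change drug to its ATC
level-4 class, with all insulins rolled up into "insulins alone or in
combination" and A10BD codes reported as named component pairs.

## Adherence (CMA)

Medication adherence is the continuous multiple-interval measure of
medication availability: the percentage of the follow-up window
`[index_date, follow_up_end)` covered by dispensed supply. The default
**carry-over** construction sweeps dispensations in date order; each
supply interval starts at the later of its dispensation date and the
exhaustion of all previously accumulated supply, so an early refill is
shelved rather than lost, overlapping supplies stack, and coverage —
truncated at the window end — can never exceed 100 %. This is the
"multiple-interval" semantics; a crude `simple_ratio` variant (sum of days
supplied over window length, optionally uncapped) is retained for
sensitivity analysis and equals the carry-over value exactly when no
supplies overlap and none crosses the window end.

Conventions: a dispensation on the window's last day contributes zero
covered days (its supply lies outside the observation window); fractional
DDD totals stay fractional until display; for patients on several
concurrent ADs the default pools all AD supply into one stream, yielding a
single per-patient CMA (a per-drug average is a deliberate non-default
alternative, since a single availability measure matches one-per-patient
reporting). Strata are closed at their lower edges: adherent at CMA ≥ 80,
partially adherent at 40 ≤ CMA < 80, non-adherent below 40. Medians and
quartiles everywhere use linear interpolation between order statistics
(`stats::quantile` type 7), fixed so that tests are reproducible.

## Significance tests and rounding

Subgroup tables use the Pearson chi-square test of independence without
continuity correction (gender × subgroup) and one-way ANOVA (age ×
subgroup), both delegated to base R's `chisq.test` and `lm`/`anova` and
cross-checked in the test suite against textbook formula oracles to 1e-9.
A zero margin is an error naming the degenerate margin; identical values
in every ANOVA cell give F = 0 by convention with a warning. Printed
percentages, ages and CMA values round half-up to one decimal; p-values
below 0.01 print as "<0.01" with raw values kept in machine output.

## Synthetic data

`generate_population()` emulates the statistical structure the analysis
assumes, not any real population. Eight archetypes are planted in
configurable proportions; the default mix (55 % prevalent users, 18 %
naïve monotherapy, 1.5 % first-line combination, 5 % add-on, 2.5 % switch,
0.5 % switch-then-discontinue, 10 % sporadic users, 7.5 % decedents)
mirrors the attrition shape of a typical AD dispensing database, where
most dispensing patients are prevalent users and naïve initiators are a
small minority. Index drugs for naïve monotherapy draw from the observed
single-index-drug distribution (83.2 % metformin, then sulfonylureas,
insulins, and the newer classes at a few percent each).

Adherence behaviour is modelled through **refill gaps**, the only
observable in dispensing data: consecutive dispensations are spaced
`days supplied / target CMA` days apart (default supply 28 DDD per
dispensation), plus uniform jitter of ±3 days by default. At zero jitter
the planted CMA is exact — the derived test plants 100 monotherapy
patients at target 0.8 and verifies every computed CMA equals 80 % — and
the full pipeline recovers every planted archetype label, which is the
package's round-trip validation. Comorbidity co-dispensations are
independent per-condition Bernoulli draws at the monotherapy-subgroup
prevalence profile, one dispensation per drawn condition at a uniform
date.

What the generator does **not** emulate: joint age–sex structure beyond
configured marginals, seasonality and stockpiling, dose titration,
multiple concurrent pharmacies, geographic structure, or correlated
comorbidity burdens. Passing round-trip tests therefore show that the
pipeline's rules are implemented correctly, not that they are robust to
real-data messiness such as irregular refill behaviour or miscoded rows
(the reader validations cover the latter separately).

`make_study_fixture()` builds fully deterministic streams that replant
published marginal counts (a 289-patient two-drug intensification block
split 189/92/8; subgroup sizes 931/289/92/31/18; 103 nine-day combination
initiators among 1464 metformin-index patients; a 1927-patient enrolment
table with 1090 males and 1759 single-index-drug patients), so the
selection and classification rules can be verified against printed
percentages exactly. Fixture patients use a fixed 35-day refill gap and
staggered 2019 index dates, and satisfy every inclusion filter by
construction.

## Problem sizes and runtime

The test suite runs the fixtures end-to-end (up to 1927 patients, ~75k
rows), the generator round-trip at 1000 patients, the ledger/idempotence
property at 5000 patients, and 200 randomized CMA schedules against an
independent daily-stock enumeration oracle; the whole suite completes in
about half a minute on one CPU. These sizes were chosen as the smallest
that exercise every rule and boundary with comfortable statistical margin.

## Known limitations

- Dispensation is not ingestion: CMA is a proxy for adherence.
- The DDD-based day of supply misstates exposure where prescribed doses
  deviate from one DDD/day (notably insulins).
- "Discontinuation after switching" depends on the declared 90-day grace
  period; sensitivity to that choice is the user's to explore via
  `study_config()`.
- The chronic-use filter applied to complete post-index calendar years
  slightly favours patients whose therapy persists to the study end; a
  follow-up-prorated variant would need a proration rule the design does
  not define.
- No persistence (time-to-gap) or outcome linkage is implemented; the
  package describes utilization, not effectiveness.
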