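---
title: "Methods: constructing observable medication use time in nursing-home claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing observable medication use time in nursing-home claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhobs)
library(data.table)
```

## The estimand and why person-time, not persons

For a US nursing-home (NH) resident, a prescription dispensing can
appear in Medicare Part D claims only on days when three conditions
hold simultaneously: the resident is enrolled in fee-for-service
Medicare Parts A and B plus Part D (and not in a managed-care plan,
whose encounter data are incomplete); the day is not covered by a
Part A post-acute skilled-nursing (SNF) bundled payment; and the
resident is not hospitalized. We call such days *observable medication
use time*. Everything this package computes reduces to classifying each
NH day on those three axes and reassembling the surviving days into
contiguous intervals.

The classical alternative — restricting to "long-stay" residents with
more than 100 days in the facility, because Part A covers at most 100
SNF days — classifies *people*, not days. It discards observable days
early in a stay, misses residents who cycle in and out of Part A
coverage after day 100, and conditions follow-up on surviving to
day 101, inviting immeasurable-time and collider-type selection biases.
The day-level classification makes the unobservable periods explicit so
they can be removed from denominators or modelled as time-varying
covariates.

## Episode construction (Step 1)

Episodes are built from MDS-style records in person-period format:
`entry` and `discharge` tracking records (discharges carry the A0310F
disposition: 10/12 = return not anticipated, 11 = return anticipated)
and `admission_assessment` records.

*Entry-anchored* episodes pair each entry with the next discharge on or
after it; an entry with no subsequent discharge means the resident was
still in the facility, and the episode closes at the study end date.
This anchoring captures the maximum MDS-documented NH time.

*Admission-assessment-anchored* episodes (the default reporting basis)
require an admission assessment and end at the first discharge with
code 10 or 12, or at a code-11 discharge with no reentry within
30 days. A reentry record dated at most 30 days after the code-11
discharge continues the same episode; a later return needs a fresh
admission assessment. The 30-day window follows MDS/CMS guidance that a
return beyond 30 days is a new admission, and we measure it as
`reentry_date - discharge_date <= 30` (both endpoints inclusive), since
the guidance does not spell out endpoint handling.

Overlapping episodes of the same anchoring (one episode's entry on or
before another's discharge) collapse to first-entry/last-discharge via
a single cummax scan over start-sorted intervals; merging is idempotent
and order-insensitive, and is verified in the tests against a
brute-force day-set union. All episodes are truncated at the recorded
death date; episodes that begin after a recorded death are dropped with
a warning rather than silently, preserving the day-accounting
invariants. Orphan discharges (no preceding entry) are skipped with an
audited count for the same reason.

Three points were genuinely open and decided as follows:

* **Day 1 of an admission-anchored episode** is the entry date of the
  nearest entry record on or before the anchoring assessment (falling
  back to the assessment date when none exists). The assessment
  certifies the admission but the resident's NH time starts at entry;
  both behaviours are available because the fallback only engages when
  no entry exists.
* **Out-of-facility gap days** between a code-11 discharge and a
  within-window reentry stay inside the episode span by default — they
  are almost always hospital days and are removed by the Step-4 flag
  anyway. The stricter convention is available via
  `drop_gap_days()` / `drop_out_of_facility_gaps = TRUE`. Note that
  under the default, the invariant "admission-anchored days are a
  subset of entry-anchored days" can fail precisely on those gap days
  (they belong to no entry-discharge pair); the containment property is
  therefore tested under the stricter convention, where it holds.
* **Interval convention**: episodes are closed date intervals, entry
  day = NH day 1, and the end date counts as an NH day (an
  entry/discharge tie is a 1-day episode). `count_discharge_day =
  FALSE` drops the final day of discharge-ended episodes for
  sensitivity analyses.

## Day classification (Steps 2–4)

The day grid carries one row per resident, episode and calendar day.
Enrollment is assessed at calendar-month granularity, matching the
layout of Medicare enrollment summary files: a day is enrolled when its
month has Part A = B = D = 1 and managed care = 0. Months absent from
the table are *unenrolled* — observability is never claimed without
evidence. A daily-interval enrollment input is also accepted
(`granularity = "daily"`) since some sources resolve enrollment to
days.

Part A stays (SNF or inpatient) cover the half-open interval
`[admit, discharge)`: `length_of_stay = discharge - admit`, and the
discharge day belongs to the next care setting. This matches claims
accounting and makes the imputation of missing discharge dates an
identity: `discharge = admit + length_of_stay`. Stays missing both
fields cannot be placed and are rejected into an error record.
Overlapping stays of one type act as their union; flags of different
types are set independently, so flagging order cannot matter (verified
by permutation tests). `include_discharge_day = TRUE` switches to
closed stay intervals for sensitivity analyses.

## Observable-time reconstruction (Step 5)

Days with `enrolled = 1, snf = 0, hospital = 0` are kept; removal
counts are logged per reason, with SNF and hospital counted among
*enrolled* days (a single enrolled day under both increments both,
mirroring stepwise attrition accounting where the two removal rows can
double-count). Maximal runs of consecutive dates within one parent
episode become observable episodes: no gap is bridged — not even one
day, since the definition of a continuous observable period admits no
tolerance — and runs never span a discharge/readmission boundary even
when dates are adjacent, because observable time is stored per resident
*and per NH admission*.

Time-since-admission bins partition `day_index`: 1–30, 31–60, 61–100,
101+. Day 101 is the conventional long-stay boundary (Part A pays 100%
of SNF days 1–20 and 80% of days 21–100).

## The long-stay comparator

`classify_long_stay_method2()` implements the day-count convention: an
admission episode is long-stay once it reaches `day_index >= cutoff`
(default 101), deliberately ignoring the observability flags — the
comparison *is* the point. Published long-stay rule sets differ in
details (qualifying assessments, cumulative vs consecutive days) that
are not restated here; this classifier is the day-index approximation,
with `attribution = "from_cutoff"` (long-stay person-time = days at or
beyond the cutoff) or `"whole_episode"`. Monthly comparisons count
residents with at least one qualifying day in the month, since a
cross-sectional "residents in month m" is otherwise ambiguous;
single-index-day counts can be had by passing a one-day month of
interest through the day grids directly.

Percentages are rounded to one decimal *half away from zero*
(`pct_round()`), not banker's rounding — this is the convention that
reproduces published stepwise percentages from their printed
numerators and denominators, which the acceptance checks verify. Zero
denominators yield `NA`, never zero.

## The synthetic generator: what it does and does not emulate

`generate_cohort()` produces the four linked tables with the structural
features the algorithm must handle. Defaults are the study conditions
where published margins exist, and documented placeholders elsewhere:

| parameter | default | basis |
|---|---|---|
| study window | 2013-01-01 .. 2020-12-31 | the cohort's observation window |
| admissions per resident | `1 + Poisson(0.5)` (mean 1.5) | published mean 1.5 admissions |
| NH length of stay | lognormal, `meanlog = log(31)`, `sdlog = 1.75` | matches published median 31 d and mean ≈ 145 d; the implied IQR is wider than published, so the tail is somewhat heavier |
| SNF lead-in | 70% of admissions; lognormal median 25 d, capped at 100 d and at the episode length | not published at this granularity; placeholder exposed as a parameter |
| hospitalizations | 1 per person-year in the NH; lognormal median 5 d | placeholder, exposed |
| reentry pairs | 20% of long-enough episodes; gap uniform on 1–45 d | straddles the 30-day boundary by construction |
| enrollment gap / managed care | 5% / 25% per resident-month | plausibility choices; managed-care penetration of roughly a quarter matches the period |
| death | 30% of residents, within 0–30 d of final discharge or inside an open episode | exercises truncation on both sides |
| blanked discharge dates | 5% of Part A stays | exercises the imputation path |

Stays that would run past the study end are emitted with a blank
discharge date and the true length of stay — the censoring pattern of
real extracts — rather than clipped. Identical parameters (seed
included) reproduce byte-identical tables; the generator's output
always passes `validate_tables()` and the episode builder (a property
tested over random parameter draws).

What the generator does **not** emulate: realistic marginal
distributions of diagnoses, facilities or payments; *persistent*
managed-care enrollment (the per-month flag churns independently, so
simulated long-stay residents lose more months to managed care than
real ones — simulated observability shares are not calibrated to the
published ones and should not be read as estimates); assessment
scheduling beyond entry/admission/discharge; and Part A benefit
exhaustion or coinsurance phases. Passing tests therefore demonstrate
the *correctness of the day accounting* under structurally realistic
inputs, not distributional fidelity to the national cohort.

## Numerical and degenerate-input choices

* Dates are integer days (`data.table::IDate`); unparsable dates are
  errors at the boundary, never silent `NA`s.
* An empty cohort flows through every step and yields empty outputs and
  an all-zero attrition row with absent (NA) percentages.
* A length-of-stay of 0 gives a same-day stay that covers no grid day
  under the half-open convention.
* Ties within a day are processed entry → assessment → discharge, so an
  entry/discharge tie is a 1-day episode.
* Resident-to-partition assignment uses a self-contained FNV-1a string
  hash, so partitioning is stable across sessions and platforms; every
  step is per-resident, which makes the pipeline embarrassingly
  parallel and its output provably invariant to the partition count
  (tested for 1/4/16).

## Verification strategy and problem sizes

The suite checks every operation against independent oracles: interval
merging against brute-force day-set unions; the flag grid against a
literal per-resident, per-day, per-record scan; run reconstruction
against a sequential walk; and the published stepwise counts against
the printed percentage and bin-sum identities. Conservation identities
(unenrolled + enrolled = total; bin sums = overall; run day-sums =
observable day count; expansion round trips) run on every simulated
cohort. Oracle-equivalence runs use 200 random cohorts of up to 8
residents over a one-year window — small enough for the brute-force
scan to stay exact and fast, large enough to hit reentries, deaths,
censored stays and enrollment churn in combination — and the
end-to-end acceptance script uses 150 residents over the full 8-year
window.

## Known limitations

* The enrollment month-to-day broadcast assumes within-month constancy;
  mid-month enrollment changes need the daily-interval input.
* The long-stay comparator is a day-count approximation of published
  person-level rules, configurable but not a reimplementation of any
  specific one.
* Dispensing-based prevalence uses the naive coverage interval
  `[fill, fill + supply - 1]` with no stockpiling or grace-period
  logic; exposure modelling is out of scope.
* Nonprescription drugs, out-of-pocket fills and other unbilled
  channels are unobservable by construction, whatever the flags say.
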