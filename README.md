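# nhobs

Observable medication use time for nursing-home residents in linked
administrative claims.

## The problem

Medicare claims are the workhorse data source for studying medication
use among US nursing-home (NH) residents, but prescription dispensings
only appear in Part D claims on days when they can be billed
individually. Days spent under Part A post-acute skilled nursing care
(SNF; a bundled payment covering up to 100 days), days spent in hospital,
and days without fee-for-service Parts A+B plus Part D enrollment are
*unobservable*: no dispensing can appear, no matter what the resident
takes. Classifying residents as "short-stay" vs "long-stay" with a
101-day length-of-stay cutoff — the common workaround — discards
observable person-time early in the stay and is a source of immeasurable
time, selection and immortal time bias.

`nhobs` implements a person-*time* (rather than person-level)
classification. For each resident it:

1. builds NH episodes from Minimum Data Set (MDS) style tracking and
   assessment records — entry-anchored, or admission-assessment-anchored
   with the A0310F end rules (codes 10/12 end an episode; code 11,
   "return anticipated", ends it only if no reentry occurs within
   30 days), merging overlapping episodes to first-entry/last-discharge,
   closing open episodes at study end and truncating at death;
2. expands episodes to a resident-day grid (`day_index` 1 on the entry
   day) and flags every day on three axes: enrolled (Parts A+B+D, no
   managed care, by calendar month), SNF-covered, and hospitalized —
   Part A stays cover the half-open interval `[admit, discharge)`, and
   missing discharge dates are imputed as `admit + length_of_stay`;
3. removes unobservable days (`enrolled = 1 & snf = 0 & hospital = 0`
   is kept) and reconstructs maximal runs of consecutive observable
   dates as *observable episodes*, never bridging a gap or a
   discharge/readmission boundary;
4. reports stepwise attrition by time-since-admission bins (days 1–30 /
   31–60 / 61–100 / 101+), a configurable day-count long-stay
   comparator, monthly algorithm comparisons, and drug point prevalence
   within observable time.

Since the source data live under data-use agreements, the package also
ships a seeded synthetic claims generator (`generate_cohort()`) with the
structural features the algorithm must survive — SNF lead-ins,
mid-episode hospitalizations, 30-day reentry pairs, enrollment churn,
deaths, censored discharge dates — plus hand-auditable fixtures
(`make_fixture()`).

## Worked example

One resident enters the NH on 2017-03-01 with a 20-day SNF lead-in, is
hospitalized May 10–16, and is discharged (A0310F = 10) on 2017-08-31:

```r
library(nhobs)
fx   <- make_fixture("figure1_schematic")
eps  <- build_episodes(fx)                       # Step 1
days <- classify_days(expand_to_days(eps), fx)   # Steps 2-4
obs  <- select_observable_days(days)             # Step 5
build_observable_episodes(obs)
#>    resident_id episode_id observable_episode_id start_date   end_date n_days
#> 1:          F1     F1-E01            F1-E01-O01 2017-03-21 2017-05-09     50
#> 2:          F1     F1-E01            F1-E01-O02 2017-05-17 2017-08-31    107
summarize_attrition(days)[, .(bin, total_days, snf_days, hospital_days,
                              observable_days, pct_observable_of_enrolled)]
#>       bin total_days snf_days hospital_days observable_days pct_observable_of_enrolled
#> 1:   1-30         30       20             0              10                       33.3
#> 2:  31-60         30        0             0              30                      100.0
#> 3: 61-100         40        0             7              33                       82.5
#> 4:   101+         84        0             0              84                      100.0
#> 5:    all        184       20             7             157                       85.3
```

The 184-day episode loses its 20 SNF days and 7 hospital days; the
157 observable days split into two runs because the hospitalization
breaks the sequence. Only a third of the first 30 days is observable
while nearly all of the 101+ tail is — the pattern that motivates
day-level rather than cutoff-based classification.

The same chain runs end to end, partitioned by resident-id hash (output
is invariant to the partition count):

```r
res <- run_pipeline(pipeline_config(sim = sim_params(n_residents = 100, seed = 7),
                                    n_partitions = 4))
res$attrition
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/nhobs.R simulate --out-dir tables --n-residents 100 --seed 7
Rscript inst/cli/nhobs.R run --in-dir tables --out-dir out --n-partitions 4
```

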