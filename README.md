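# oatepisodes

Constructing opioid agonist therapy (OAT) treatment episodes from pharmacy
dispensation records.

## The problem

Claims databases record what pharmacies dispense — a drug code, a service
date, a days supply, a quantity, a strength — but outcomes research on
opioid use disorder needs treatment *episodes*: continuous spans of
methadone, buprenorphine/naloxone, slow-release oral morphine (SROM) or
injectable OAT (iOAT) therapy, with switches and concurrent use identified
rather than averaged away. Fixed-gap episode definitions handle neither
overlapping coverage (early refills, split doses, cross-tapers) nor
multi-drug therapy well.

`oatepisodes` implements an episode-construction framework with three
parts:

* **Allen's interval algebra** — each dispensation covers a half-open
  integer-day window `[start, start + days_supply)`; any ordered pair of
  windows stands in exactly one of 13 temporal relations (*meets*,
  *before*, *overlaps*, *starts*, *finishes*, *contains*, *equals* and
  inverses), decided by `allen_classify()`.
* **Temporal margins** — a same-drug overlap of at most ε = 7 days is an
  early refill: the later record is shifted forward and the relation
  recoded *overlaps* → *meets*. Between different drugs, co-dispensation
  of at most ε = 14 days is a transition; longer co-dispensation is
  multitherapy and is left untouched.
* **Drug-specific permissible gaps** — an uncovered gap beyond G_d days
  discontinues the episode (methadone and SROM 5, buprenorphine/naloxone
  6, iOAT 3), mapped onto the *before* relation so the discontinuation
  window stays independent of the overlap margin.

Episodes come out typed as monotherapy, transition, multitherapy or
transition-multitherapy, with dose segments, switch events, co-dispensation
lengths and bridged hospital days attached. The package also ships the
upstream cleaning rules (split-dose consolidation, quantity-per-day repair,
days-supply capping), a hospitalization-bridging step, a seeded synthetic
claims generator with ground-truth episodes, and reporting helpers.

## Worked example

```r
library(oatepisodes)
library(dplyr)

d <- bind_rows(
  dispensations("p1", "methadone", start = c(0, 7, 14, 25), days_supply = 7),
  dispensations("p2", "srom",      start = 0,  days_supply = 20),
  dispensations("p2", "methadone", start = 14, days_supply = 16),
  dispensations("p3", "methadone", start = 0,  days_supply = 40, quantity = 4000),
  dispensations("p3", "srom",      start = 10, days_supply = 30)
)

ep <- build_episodes(d)
tidy(ep) %>%
  select(episode_id, start, end, type, drug_sequence,
         duration_days, n_switches, max_co_dispensation_days)
#> # A tibble: 3 × 8
#>   episode_id start   end type         drug_sequence  duration_days n_switches
#> 1 p1-1           0    32 monotherapy  methadone                 32          0
#> 2 p2-1           0    36 transition   srom;methadone            36          1
#> 3 p3-1           0    40 multitherapy methadone;srom            40          0

switch_events(ep)
#> # A tibble: 1 × 6
#>   person_id episode_id   day from_drug to_drug   mechanism
#> 1 p2        p2-1          20 srom      methadone short_overlap_recode
```

Person p1's four fills include a 4-day gap (within methadone's 5-day
permissible gap) and stay one monotherapy episode spanning days 0–32.
Person p2's methadone overlaps the tail of their SROM by 6 days — within
the 14-day cross-drug margin — so the methadone is shifted to abut the
SROM (day 20), a switch event is logged, and the episode is a transition.
Person p3's SROM is co-dispensed with methadone for 30 days, beyond the
margin: a multitherapy episode with intervals untouched.

`glance(ep)` gives the one-row cohort summary (episode counts, type
percentages, duration quartiles); `autoplot(ep)` draws coverage and
episode spans; `episode_assignments(ep)` returns the record-level mapping
(shifted intervals, assigned drug, exclusions).

Upstream and downstream pieces compose the same way:

```r
raw     <- read_dispensations("dispensations.csv", read_drug_catalog("catalog.csv"))
cleaned <- clean_dispensations(raw)
stays   <- read_hospitalizations("stays.csv")
ep      <- build_episodes(cleaned$dispensations, episode_config(), stays = stays)
episode_type_distribution(ep)
co_dispensation_patterns(cleaned$dispensations)
margin_sensitivity(cleaned$dispensations, epsilons = c(0, 7, 14))
```

A thin command-line wrapper with `clean`, `classify`, `episodes`,
`simulate` and `summarize` subcommands is installed under
`inst/cli/oat.R`.

## Synthetic cohorts

Real OAT claims are access-restricted, so the package carries a seeded
generator whose defaults emulate observed dispensing: per-drug relation
mixtures (`oat_relation_mixtures()`), realistic days-supply ranges, gap
behaviour, cross-drug transition and multitherapy patterns, hospital
stays, and injectable error types for exercising the cleaning rules.
`generate_cohort()` returns the corrupted table *and* the ground truth
(episode list, relation categories, error ledger), and
`build_episodes()` recovers the generated episodes exactly on noise-free
output — the property the test suite leans on.

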