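---
title: "Constructing OAT treatment episodes from dispensation records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing OAT treatment episodes from dispensation records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatepisodes)
library(dplyr)
```

## The problem

Opioid agonist therapy (OAT) — methadone, buprenorphine/naloxone,
slow-release oral morphine (SROM), and injectable OAT (iOAT) — is the
standard treatment for opioid use disorder, and pharmacy claims databases
are the main source for studying its outcomes at population scale. A claim
records what was *dispensed*: a drug code, a service date, a days supply,
a quantity and a strength. Outcomes research, however, needs treatment
*episodes*: continuous spans of therapy with a start, an end, and a
characterisation of what happened inside (one drug, a switch, concurrent
drugs).

The common approach — declare an episode broken whenever the gap between
consecutive fills exceeds a fixed allowance — ignores two things real
dispensing data are full of: overlapping coverage (early refills, split
doses, witnessed same-day dispensing, cross-tapering) and the use of more
than one OAT medication, either sequentially (a switch) or concurrently
(multitherapy). This package implements an episode-construction framework
built from three parts:

1. **Allen's interval algebra.** Every dispensation covers a half-open
   integer-day window `[start, start + days_supply)`. Any ordered pair of
   such windows stands in exactly one of 13 temporal relations — *meets*,
   *before*, *overlaps*, *starts*, *finishes*, *contains*, *equals* and
   their inverses (*equals* is self-inverse). `allen_classify()` decides
   the relation from the endpoint orderings; under the half-open
   convention, back-to-back supplies (`x_end == y_start`) share no covered
   day and no gap, which is exactly *meets*.
2. **Temporal margins (epsilon).** The algebra says *whether* two windows
   overlap, not for how long. A margin converts short overlaps into
   continuity: a same-drug overlap of at most `epsilon_same` (default 7
   days) is an early refill, so the later record is shifted forward to
   abut the earlier one and the relation is recoded to *meets*; longer
   overlaps are kept, so episodes are not artificially extended. Between
   *different* drugs a second margin `epsilon_cross` (default 14 days)
   separates a transition (cross-taper, low-dose induction) from genuine
   multitherapy.
3. **Permissible gaps.** Discontinuation is drug-specific, reflecting
   half-lives and dispensing practice: an uncovered gap of more than 5
   days (methadone, SROM), 6 days (buprenorphine/naloxone) or 3 days
   (iOAT) ends the episode. Gaps map onto the *before* relation, so the
   discontinuation window stays separate from the overlap margin.

The result is four episode types: **monotherapy** (one drug throughout),
**transition** (a switch with continuity of care), **multitherapy**
(co-dispensation beyond the cross-drug margin), and
**transition-multitherapy** (both in one episode).

## The state machine

`build_episodes()` sweeps each person's records chronologically while
maintaining a set of *active drug threads*, one per drug in current use.

For a record of a drug with an active thread, the monotherapy rules apply
against the thread's *frontier* (the record reaching furthest into the
future, after any shifts): *meets* and within-gap *before* continue;
*before* beyond the gap is unreachable inside an episode because the
thread would already have expired; an overlap of at most `epsilon_same`
shifts the record forward (days supply preserved — shifts therefore
cascade along chains of early refills, and the sensitivity report below
measures that); longer overlaps are retained with doses summed over the
shared days; nested relations (*starts*, *finishes*, *contains*,
*equals*) are aggregated — the dose is added over the nested period, and
total dispensed milligrams are conserved.

For a record of a drug without an active thread, the cross-drug rules
apply against the latest active thread:

* *meets*, or *before* within the **previous** drug's permissible gap —
  a switch; the old thread closes, a new one opens.
* partial overlap of at most `epsilon_cross` — recoded to *meets*, a
  switch.
* partial overlap beyond `epsilon_cross` — both threads stay active;
  the co-dispensation is real.
* the new record nested inside the frontier with co-dispensation at most
  `epsilon_cross` — absorbed into the encompassing drug's thread (a
  failed or incidental induction attributed to the dominant therapy).
  When the *new* record encompasses the frontier instead, the frontier
  record is re-attributed to the encompassing drug; if the old thread had
  prior records a switch event is logged so episode typing stays
  well defined.
* *equals* with duration at most `epsilon_cross` — both records are
  excluded and flagged; the data cannot say which of two identical
  same-day windows represents the therapy, and choosing a survivor would
  be arbitrary.
* anything longer-equal than the margin — multitherapy, intervals
  untouched.

An episode closes when every active thread has been silent for longer
than its own drug's permissible gap; with a single thread this is exactly
"the permissible gap of the last medication dispensed". Typing is decided
at close from two facts: whether any switch event occurred, and whether
the maximal co-dispensation segment (computed from the retained,
post-shift intervals) exceeds `epsilon_cross`. An episode with two drugs,
no switch and no long co-dispensation cannot arise from these rules; the
code defensively labels such an episode multitherapy.

```{r}
d <- bind_rows(
  dispensations("p1", "methadone", start = c(0, 7, 18), days_supply = 7),
  dispensations("p2", "srom", start = 0, days_supply = 20),
  dispensations("p2", "methadone", start = 14, days_supply = 16)
)
ep <- build_episodes(d)
tidy(ep)
switch_events(ep)
```

## Hospitalizations

Outpatient claims omit inpatient dispensing, so a hospital stay can cut a
hole in an ongoing episode. When an admission falls inside an episode's
span or inside its closing drug's permissible gap, therapy is assumed to
continue: the gap clock restarts at discharge, and any OAT dispensation
within the closing drug's gap after discharge merges the would-be-separate
episodes (a drug change across the bridge is a switch). Bridged days are
reported per episode (`bridged_hospital_days`) so duration can be
recomputed under either convention — with or without inpatient time.
Scenarios the data cannot adjudicate (therapy initiated *de novo* in
hospital, regimen changes decided before admission) are out of scope; the
three implemented rules are toggleable via
`episode_config(bridge_hospitalizations = )`.

## Cleaning rules

Raw tables carry pharmacy-workflow artefacts. `clean_dispensations()`
applies three corrections, in a fixed order, each with a full audit trail:

1. **Consolidation** of split doses: same person, drug and service date
   rows merge (quantities summed, days supply the maximum). Discordant
   strengths block the merge — summing across potencies would fabricate a
   dose — and are flagged instead.
2. **QPD repair**: a row whose quantity-per-day deviates from the median
   of its adjacency window (2 records each side, same person and drug) by
   more than a factor of 2 is repaired — first by recomputing days supply
   from the quantity when that lands in the plausible 1–28-day range
   (OAT spans daily dispensing to a monthly depot injection), otherwise
   by resetting the quantity to the window's daily rate. Rows with fewer
   than two untouched neighbours are left alone; with an even window the
   lower median is used, which never inflates a dose. Rows corrected by
   any cleaning rule are neither re-judged nor used as references, so the
   pipeline is stable under re-runs.
3. **Supply capping**: a days supply that overruns the next same-drug fill
   is reset to the inter-fill distance (minimum one day); the last record
   of a sequence is never capped, and quantity is never changed here.

The order matters: capping must see consolidated dates, and QPD repair
should judge the supplies as dispensed. The deviation factor, window
width and plausible range are configuration (`cleaning_config()`), not
constants — the precise thresholds used on any given source system are a
data-governance decision, and these defaults are documented stand-ins.
Free-form editing of service dates is deliberately not implemented:
without an external reference it amounts to silent data fabrication.

## The synthetic cohort generator

Restricted claims data cannot ship with a package, so the generator
(`generate_cohort()`, `simulate_relation_stream()`) produces cohorts with
known ground truth. Its defaults are the study conditions the machinery
is built for:

* per-drug relation mixtures from `oat_relation_mixtures()` — the
  observed eight-category distributions in a large provincial cohort,
  with *before* dominating everywhere (methadone 99.43%) and *equals*
  pronounced for buprenorphine/naloxone (21.46%) and SROM (20.87%);
* days-supply ranges of 1–3 days (iOAT), 1–7 (methadone, SROM) and 7–28
  (buprenorphine/naloxone, including the monthly depot);
* *before* gaps drawn within the drug's permissible gap, with a 15%
  chance of a long gap (up to 60 days beyond it) that genuinely breaks an
  episode — a rate chosen to produce the short, frequently interrupted
  episodes typical of OAT claims;
* optional cross-drug tails (5% transitions, 3% multitherapy) and
  injectable error types (split doses, QPD outliers, supply overruns) at
  configurable rates, zero by default;
* uniform per-drug daily doses; dose realism is non-critical because the
  episode logic uses doses only for segment bookkeeping.

Two design points matter for what the tests can claim. First,
`realize_relation()` is the constructive inverse of the classifier, and
intervals are realized against the *immediately preceding record*, not
the running coverage frontier; with a stable chronological sort this
makes re-annotation recover the sampled relation categories *exactly*, so
mixture-recovery checks measure only multinomial sampling noise.
Categories structurally infeasible against a short previous record
(e.g. *contains* after a 1-day fill) are redrawn from the mixture — a
negligible perturbation at the observed category rates. Second, the
generator derives its ground-truth episodes from a deliberately plain
linear replay of the linking rules (a frontier interval, a shift rule and
a gap check in a dozen lines), kept separate from the thread-based state
machine it is used to test.

What the generator does not emulate: calendar-time policy shifts, dose
tapering, person-level covariates, or the correlation structure of real
pharmacy workflows. Passing the recovery tests therefore shows the
machinery is internally correct under the stated mixtures and ranges, not
that any particular real cohort will exhibit the same episode-type
proportions.

```{r}
sim <- generate_cohort(sim_config(n_persons = 50), seed = 1)
built <- tidy(build_episodes(sim$clean_dispensations))
all(built$type == sim$truth_episodes$type)
glance(build_episodes(sim$clean_dispensations))
```

## Reporting

`relation_frequencies()` tabulates consecutive-pair relations per drug in
the eight-category scheme (inverse labels fold onto their base relation:
a record that *finishes* its predecessor's coverage is counted under
*finishes*). `co_dispensation_patterns()` finds maximal multi-drug
coverage segments and labels each by the surrounding therapy — return
(`A -> (A+B) -> A`), switch (`A -> (A+B) -> B`) or other — with duration
summaries. `margin_sensitivity()` reruns the same-drug recoding cascade
at several margins and summarises the service-date shifts; with no margin
the shifts accumulate without bound over stacked overlaps, while a small
margin collapses them, which is the empirical argument for the 7-day
default. `episode_type_distribution()`, `tidy()`, `glance()` and
`autoplot()` summarise the episode set itself.

```{r}
margin_sensitivity(sim$clean_dispensations, epsilons = c(0, 7, 14)) %>%
  filter(drug == "all")
```

## Numerical conventions and edge cases

* **Half-open day windows.** The source data are date-resolved;
  time-of-day is discarded. The end date is exclusive, a documented
  convention: it makes *meets* coincide with back-to-back supplies and
  leaves no residual cases in the classification (every ordered pair of
  non-degenerate windows gets exactly one of the 13 labels, verified
  exhaustively in the tests).
* **Ties.** Same-day records of different drugs are ordered by (start,
  drug name, end) for determinism. Quartiles are Tukey hinges
  (`stats::fivenum()`), the inclusive median-of-halves rule. Modal shifts
  break ties toward the smallest value.
* **Within-gap days.** Uncovered days inside a permissible gap count
  toward episode duration (the span convention); dose segments tile the
  span minus those uncovered days, so covered time is always recoverable.
  A config toggle records the choice.
* **Long same-drug overlaps** (beyond `epsilon_same`) keep both records
  with doses summed over the shared days, flagged
  `long_same_drug_overlap_retained` so sensitivity analyses can treat
  them as coverage-only instead.
* **Degenerate inputs.** Zero or negative days supply, unknown drug
  codes and unparseable dates are rejected at the door with row-numbered
  diagnostics rather than silently dropped.

## Problem sizes

The test suite runs entirely on generated data: exhaustive
classification uses all interval pairs with endpoints on a 7-point grid
(1,764 ordered pairs), property checks use cohorts of 40–60 persons
(roughly 400–700 records), and mixture recovery uses streams of
100,000 records — sizes chosen so the full suite completes in about a
minute while the binomial standard errors on recovered percentages stay
below a tenth of a percentage point.

## Limitations

Claims record dispensing, not ingestion; episodes constructed here are
exposure constructs, not verified treatment. The pairwise, sequential
logic evaluates co-dispensation against the latest active record, so
concurrency built from chains of very short fills registers through the
episode-level co-dispensation sweep rather than through any single pair.
The cleaning thresholds and the hospitalization rules are configurable
stand-ins for source-system-specific decisions, and the permissible gaps
and margins — though clinically motivated — should be recalibrated when
the framework is applied to other jurisdictions, populations or drug
classes.
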