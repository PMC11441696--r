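---
title: "Deriving treatment lines and triple-class exposure from myeloma claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving treatment lines and triple-class exposure from myeloma claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelolot)
```

## What this package computes, and why it is not trivial

Claims data record *events* — a diagnosis code on a date, an oral
prescription with a coverage window, an injectable administration on a
single day, a procedure code. Nothing in the data says where one line of
therapy ends and the next begins, what "the regimen" of a line was, or
when a patient became triple-class exposed (TCE: has received an
immunomodulatory drug, a proteasome inhibitor and an anti-CD38 antibody).
Every one of those constructs is an analyst's rule applied to raw records,
and small rule changes move headline numbers. This vignette states every
rule this package applies, the parameters that govern them, and the reasons
behind the defaults.

## Cohort rules

**Index date.** The earliest prescription date of an index drug
(bortezomib, lenalidomide, daratumumab — the agents whose first-line use
defines the population of interest) falling in the *calendar month* of the
first non-suspected C90 diagnosis or later. Month granularity is the
default because claims diagnosis onset is effectively month-precise; a
day-level comparison is a config switch (`cohort$month_granular_index`).
Suspected (rule-out) diagnosis flags are excluded from case finding by
default — standard claims-validity practice — and this too is configurable
(`cohort$exclude_suspected`).

**Funnel.** Six criteria applied in a fixed order, each reported with
entering and excluded counts that telescope: (1) a qualifying C90 record
exists; (2) an index date exists; (3) the last data record falls at least
6 *calendar* months after index (`lubridate` month arithmetic, never a
183-day approximation, so month-end boundaries behave predictably); (4) no
core anti-myeloma drug before index — dexamethasone and prednisone are
exempt, which is also why steroids are never "core" anywhere in the
package; (5) no stem-cell transplant (SCT) between the configured
exclusion start (2008-04-01) and the day before index; (6) at least one
record of any type (diagnosis, prescription or procedure) in the 3 years
before index. "Any type" is the broadest reading of a medical-record
lookback; the alternative readings would only shrink criterion-6 survival,
and the window is configurable.

**Follow-up end** is the patient's last record on/after index, of any
type. **Age** is completed years at index. **Baseline comorbidities**
match ICD-10 prefixes in `[index − 6 months, index − 1 day]`; the shipped
prefix map (renal N17–N19; liver K70–K77; cardiac I20–I25, I30–I52;
pulmonary J40–J47, J96; vascular I10–I15, I70–I79; back pain M54; dementia
F00–F03, G30) is a reconstruction of common claims practice and is meant
to be replaced by site-specific code lists in the config.

## Line-of-therapy rules

**Coverage.** Oral prescriptions cover their inclusive start–end window.
Injectable administrations are single-day records; each is imputed to
cover `injectable_coverage_days` = 28 days, a typical cycle length. Claims
carry no persistence information for injectables, so *some* imputation is
unavoidable; 28 days keeps weekly, biweekly and four-weekly schedules
continuous while letting true treatment-free gaps appear quickly.
Overlapping or touching windows of the same drug merge.

**Line transfer.** The default trigger (T1) opens a new line at the first
core-drug start date preceded by `gap_threshold_days` = 90 days with no
core-drug coverage at all. A novel-class trigger (T2: a core drug of a
class absent from the current line starting after the formation window) is
implemented but off by default, because within-line regimen *bridging* —
e.g. Vd transitioning to DRd inside the first line — is a real and
clinically reported phenomenon that a class trigger would forbid by
construction. Both the threshold and the trigger are config keys. Ties:
several core drugs starting the same day after a qualifying gap open one
line jointly. Steroid-only coverage never extends a line's end and never
bridges a gap. A line ends on its last core-covered day before the next
line starts (or overall); "last covered day" was chosen over "last start
date" because a line's final oral window represents real exposure beyond
its start date.

**Regimen segments.** The line's regimen label comes from every core drug
plus steroid started within the 56-day formation window, matched
*exact-set* against the catalogue (24 published doublet/triplet entries
plus the D-RVd quadruplet and SKd, both observed in practice). Exact-set
matching — an extra unlisted core drug maps to "Other" — mirrors the
published treatment of modified, steroid-uncombined or unapproved regimens
as an explicit "Other" bucket. After the window, a core-drug start or
discontinuation opens a new segment classified as add-on (strict
superset), de-escalation (strict subset) or bridge (otherwise).

**Refill grace.** Two numerical guards keep cyclic dosing from reading as
regimen change: a drug's coverage lapse of at most `refill_gap_days` = 30
days counts as continuation (longer than a one-week oral off-cycle,
shorter than the 90-day transfer threshold), and a drug stopping within 30
days of the line end is a ragged stop, not a de-escalation segment.
Without these, a 21-days-on / 7-days-off lenalidomide schedule would
generate a spurious alternation of "DRd-based" and "Dara-based" segments.

**Conditioning melphalan.** Melphalan records within ±14 days of an SCT
date are high-dose conditioning, not regimen membership; they are removed
from the episode engine's input entirely, so they neither extend coverage
nor create spurious M-containing labels. At conventional dosing (VMP,
D-VMP) melphalan participates normally. Window configurable
(`lines$conditioning_window_days`).

**Durations** are inclusive day counts divided by 30.4375 (the mean
calendar-month length), unrounded; a one-day line has positive duration.

## TCE rules

"Received a class" means at least one prescription or administration of a
drug in that class on/after index — a single day suffices. The per-line
flag at line *k* is true when the cumulative classes through the end of
line *k* cover IMiD, PI and anti-CD38; a patient counts as TCE *in* the
line whose segments complete the triple (not the following line). Per-line
percentages divide by the number of patients in that line; cumulative
percentages divide by the first-line denominator — two deliberately
different conventions, both audited. First-line TCE patients split into
quadruplet starters (the initial formation-window regimen already spans
all three classes) and sequencing patients; the pathway string is the
chronological sequence of segment labels up to the segment completing the
triple, with consecutive duplicates collapsed. The approval-era analysis
buckets first-line TCE patients by index month against month-granular era
boundaries (D-VMP 2019-08, DRd 2019-12) and uses integer-rounded
percentages, matching that analysis's reporting style.

## Summary conventions

One rounding routine serves every table: half *away from zero* at the
printed precision. Half-up is load-bearing — 56/128 = 43.75% must print as
43.8, which banker's rounding does not produce. Every emitted table
carries explicit `n` and `denominator` columns, and
`audit_percentages()` re-derives each percentage after every pipeline run.
Zero denominators yield `NA` cells with a warning rather than errors. The
transplant-group regimen table's denominators are exposed as an explicit
argument, because published induction-context denominators can restrict to
subsets (e.g. patients transplanted in that line) that the claims records
alone do not define.

## The synthetic generator

`generate_claims()` plans trajectories first — group, age, index month,
line count, per-line regimen labels, durations, between-line gaps — and
then realizes them as records: oral drugs as 21-on/7-off cyclic windows
whose last window ends exactly on the planned end; injectables as spaced
administrations (bortezomib weekly, carfilzomib biweekly, daratumumab
weekly tapering to four-weekly) whose imputed coverage stays continuous.
Ground truth is therefore known by construction and emitted as a sidecar
the pipeline never reads. Scenario defaults describe the study conditions
the pipeline targets: roughly 7% transplant patients, elderly
non-transplant patients (mean 75, range 37–94) versus younger transplant
patients (mean 60, range 35–73), first-line mixes led by Rd/Vd/RVd
(non-transplant) and RVd (transplant), most patients stopping after one or
two lines, a ~10% first-line bridging rate over the common pathways
(Vd→DRd, RVd→DRd, Rd→DVd) and a ~1% quadruplet-start rate, and index
months spread over 2015–2020. Planted ineligible patients violate exactly
one funnel criterion each, so funnel counts are checkable per criterion.

What the generator deliberately does not emulate: real Japanese fee
-schedule coding, dose and formulation detail, death, hospital transfers,
mid-line censoring, coding errors, or diagnosis dates that disagree with
treatment. Passing the recovery suites therefore shows that the engine
inverts its own stated rules exactly on clean data — a correctness
property — not that those rules recover the "true" clinical lines in a
real, messier database, where gap lengths and coding quality vary.

**Gap separation matters.** Ground-truth recovery is exact because the
generator keeps between-line gaps strictly above (≥ 100 days) and
within-line lapses strictly below (≤ 30 days) the 90-day threshold. A real
cohort has no such separation guarantee; that is a property of the data,
not of the algorithm.

## Verification strategy

Three independent routes check the engine: (1) directed examples with
hand-computed answers; (2) a brute-force oracle that enumerates covered
days as explicit integer sets and applies the trigger and exposure
definitions literally, compared on 1,000 randomized small trajectories
(three drugs, 400 days); (3) planted-truth recovery on synthetic cohorts
of 500 patients (problem sizes chosen to keep the default suite fast while
exercising every rule; the marginal-fidelity check uses 2,000 patients).
Table identities — most-recent(k) = cumulative(k) − cumulative(k+1);
per-line TCE(k) = carryover(k) + newly-TCE(k); every percentage
re-derivable from counts — run on every pipeline output.

## Known limitations

* The 28-day injectable imputation and the 90-day gap threshold are
  assumptions, not facts; both shift line counts in predictable directions
  (shorter coverage or shorter thresholds split more lines). They are
  config keys precisely so sensitivity analyses can vary them.
* Month-granular diagnosis comparison admits an index prescription up to a
  month before the recorded diagnosis day.
* The exact-set catalogue treats any unlisted combination as "Other";
  site-specific regimens must be added to the config to be named.
* Per-line TCE attribution ("in the completing line") is one of two
  defensible conventions; the identity tests document which one is
  implemented.
* The engine assumes prescriptions after the index date belong to myeloma
  therapy; indication codes are not modelled.
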