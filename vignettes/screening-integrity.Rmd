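---
title: "Screening integrity: duplicate detection and quota-controlled enrollment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening integrity: duplicate detection and quota-controlled enrollment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensift)
```

## The problem

Decentralized (remote) trials recruit through online advertisements that
funnel applicants into a web screening survey. Two things go wrong at
scale. First, the same person submits the screener repeatedly — sometimes
by accident, sometimes deliberately, changing a name or email each time
to guess their way past eligibility criteria. Second, the applicant pool
that self-selects into online screening is rarely representative, so an
unmanaged first-come-first-served enrollment bakes sampling bias into the
final sample. `screensift` implements both countermeasures as a single
auditable engine over flat screening-survey exports: a criteria-based
duplicate detector with a time window, and a quota engine that admits or
defers screening-eligible candidates against enrollment minimums and
maximums.

Nothing here talks to a data-capture server; the engine consumes a CSV
export and a declarative YAML configuration, and emits CSV/JSON decision
artifacts, which makes every decision replayable after the fact.

## Duplicate detection

### Matching model

The detector's rule is a disjunction of conjunctions over *canonical*
field values, restricted to a time window:

* **AND within a criterion** — a criterion such as `{first_name,
  last_name}` fires only when every listed field agrees.
* **OR across criteria** — the pair is a duplicate pair when any
  criterion fires, e.g. *(first AND last name) OR email OR phone*.
* **Window** — only pairs submitted within `window_days` calendar days
  of one another (inclusive boundary) are compared. The shipped example
  uses 183 days for "six months"; calendar-month arithmetic is
  deliberately avoided as ambiguous. Comparison is at date resolution in
  a single configured study timezone, because day-level gap categories
  ("submitted the same day") are the reporting unit.

Matching is exact on canonical values, never fuzzy. Normalization is
what absorbs formatting noise: text fields are NFC-normalized,
case-folded and whitespace-collapsed; emails are case-folded; phone
numbers are reduced to their last 10 digits; dates are re-emitted as
ISO. Normalization is idempotent, and an empty value is *missing*;
missing never equals missing, so two blank phone fields are not evidence
of identity — otherwise every optional field would mass-flag honest
applicants. Edit-distance or phonetic matching is an extension point,
not implemented: the matching semantics are meant to be explainable to
study staff in one sentence.

### From pairs to sets, originals, and entries

Duplicate sets are connected components (size ≥ 2) of the pair graph.
Transitivity is the point: a fraudster who mutates one field per
resubmission produces a chain A–B–C where A and C share nothing
directly, yet all three are one person. Within a set, the earliest
record by `(submitted_at, record_id)` is the **original duplicate**
(ties on timestamp broken by id — the tie-break has to be stated
somewhere, and record id is the only stable choice); every later member
is a **duplicate entry**. The headline rate is
`100 × (originals + entries) / total screens`, printed to two decimals,
half away from zero.

Each entry is categorized by its day gap to the *nearest earlier*
matching record: `same_day` (0), `within_week` (1–7), `within_month`
(8–31), `over_month` (≥ 32). These boundaries follow the narrative
anchors used in published screening tallies ("same day", "more than a
month"); the exact interior cut points are this package's choice. The
per-entry field profile (which identifier fields were kept versus
changed relative to that nearest match) is likewise our reconstruction
of the published "duplicated fields" breakdown, and is labelled as
descriptive: the engine never issues a fraud verdict, it assembles
evidence for staff.

A flagged record still enters the comparison store — later resubmissions
must be able to match the whole chain — and the streaming check reports
*all* matching priors with *all* fired criteria, because the annotations
are the audit trail.

### Streaming versus batch

`flag_stream()` replays the live check (each record against all earlier
ones); `build_duplicate_sets()` works on the full batch. On simulator
output the two agree exactly: flagged records are precisely the
non-original set members. This equivalence is a property of streams in
which every duplicate matches its immediate predecessor. It can fail on
adversarial stores — a record whose only direct matches are *later*
records (edges A–C and B–C without A–B) is an entry the streaming check
cannot see at B's arrival time. The simulator never produces such
stores, because mutated values are drawn fresh and never revert; the
test suite exercises the equivalence on simulated streams and the
general caveat is stated here rather than hidden.

## Quota-controlled enrollment

A quota rule bounds enrollment of candidates matching a conjunctive
predicate (`sex = female`, or nested: `sex = female AND area = rural`)
by a count or a percent of the scope. Percent minimums round **up**
(`ceil`) — a 25% floor of 143 is 36 — and percent maximums round
**down**: the guarantee must survive rounding in the participant's
favor, not the recruiter's. The engine does not do power analysis;
choosing the bounds is the scientist's job.

Decision order for each eligible candidate, in one scope:

1. **full** — the sample (or current block) has no open slot;
2. **maximum** — admitting would exceed some maximum's effective count;
3. **reserved slots** — admitting a candidate who does not help an
   unmet minimum is refused once the open slots remaining after the
   admission would no longer cover the outstanding shortfalls;
4. otherwise **admit**, and the ledger is updated.

A candidate missing a quota field raises an error rather than a
rejection: silent rejection of malformed data would corrupt the
attainment audit.

### Overlapping minimums

With mutually exclusive predicates (the usual case — bins of one
variable), summing shortfalls is exact, and that is the default
(`reserve_mode = "independent"`). With overlapping predicates (minimums
for women and for rural participants), summing over-reserves: one
future rural woman covers both. The `"exact"` mode instead computes the
minimum number of future admissions that could cover all shortfalls,
via a greedy cover over category cells (every combination of the values
mentioned by the rules, plus an "other" level per field). Greedy set
cover is not optimal in general; for the rule families tested — where a
most-specific cell dominates the others — it matches a brute-force
breadth-first search, which the test suite verifies. Published module
behavior for competing overlapping minimums is undocumented, so both
modes are this package's design, stated as such.

Spec validation rejects configurations it can *prove* infeasible:
minimum rules that constrain a common field to pairwise different
values and whose effective counts sum beyond the scope. Overlapping
configurations that merely might be infeasible are admitted and
reported at replay time as unmet-minimum warnings — an undersupplied
recruitment stream is a study-management fact, not a crash.

### Blocks

With a `block_size`, every rule is enforced inside consecutive
enrollment blocks, which spreads quota pressure across the accrual
period and stops time from confounding group membership (all men in
year one, all women in year two). The trade-off, documented rather than
resolved: full-sample mode never turns a candidate away for a quota
that a later stretch of enrollment would have satisfied, blocked mode
can. Count amounts apply per block unchanged; the final partial block
of size *s* scales count minimums by `ceil(amount × s / block_size)`
capped at *s* (so no quota becomes unreachable), and maximums by the
matching floor — the partial-block rule is undefined in the source
material, and the ceiling/floor asymmetry keeps the minimum-guarantee /
maximum-guarantee semantics intact. A block size equal to the total is
exactly the no-blocks engine, which is property-tested.

`check_time` records whether decisions were taken at screening
completion or deferred to enrollment confirmation; the engine replays
whichever order the stream encodes and stamps the mode on every
decision. The server-side interleaving of the two is out of scope here.

## The simulator

`generate_stream()` fabricates a screening stream with ground truth,
from three populations:

* **honest** applicants: one submission each, unique fabricated
  identifiers (name pools, derived emails, random 10-digit phones, all
  collision-checked — no real personal data anywhere);
* **mistake** resubmitters: a second submission that copies every
  field, after a long gap (default: 5% same-day, positive gaps
  geometric with mean 45 days — matching adult screening tallies where
  roughly a third of duplicate entries arrive more than a month later);
* **fraud** resubmitters: 2–15 total submissions (geometric decay 0.55
  across that range; 15 matches the most prolific submitter observed in
  practice), mostly in rapid succession (default 72% same-day gap mass,
  mirroring an adolescent cohort where over 70% of duplicate entries
  were same-day; positive gaps mean 7 days), each resubmission mutating
  each identifier independently (defaults: names 0.5, email/phone 0.3).

Mutated values are drawn fresh and never revert to an earlier value:
reverting would create direct matches between non-adjacent submissions
that real fraudsters' chains do not show, and would break the
streaming/batch equivalence above for the wrong reason. Default
fractions are 15% fraud and 10% mistake identities over a 365-day
accrual window. Everything is a deterministic function of the
parameters including the seed.

What the simulator does *not* emulate — and therefore what passing
tests do not show about real data: cross-identity identifier collisions
(shared household phones or emails), typos (the engine matches exactly,
so a one-character email typo is a miss in both simulation and
reality), bots, IP/device fingerprints, and eligibility answers that
drift with re-screening. Detection recall of 1.0 on simulated streams
where fraudsters keep a criterion intact is a statement about the
engine's bookkeeping, not about real-world fraud yield; symmetrically,
the recall-0 case documents the engine's stated blind spot — a
fraudster who changes every matched field is invisible to exact
matching.

## Numerical and reporting choices

* All printed percentages round half away from zero; rates to two
  decimals (`30.90`), attainment shares to integers (`36/143 → 25%`).
  Base R's banker's rounding would print `24%` for some half-way cases
  and no published enrollment table does that.
* Window boundaries are inclusive; gap categories partition entries
  exactly (`sum(gap_counts) == n_entries` is asserted in tests).
* Determinism: equal inputs give byte-identical outputs; the only
  randomness source is the simulator seed.

Problem sizes used by the shipped test-and-verification suite: streams
of up to ~200 records for the streaming/batch equivalence (200 random
streams), 20 random arrival orders of a 520-candidate stream for quota
enforcement at the 143-participant study size, and ~2,000 simulated
duplicate entries for the gap-model calibration check (observed
same-day fraction within three standard errors of the configured
mass).

## Known limitations

* Exact matching only; no fuzzy linkage (stated extension point).
* One window for the whole criteria set, not per criterion.
* The greedy exact-reserve cover is verified optimal only for
  dominated-cell rule families; pathological overlapping rule systems
  could over-reserve by a small margin (never under-reserve a maximum).
* Blocked quotas can reject a candidate an unblocked design would have
  admitted later; this is the documented design trade-off, not a bug.
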