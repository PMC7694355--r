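---
title: "Temporal record linkage of ED visits and hospital admissions: methods"
author: "tempolink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal record linkage of ED visits and hospital admissions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempolink)
```

## The linkage model

`tempolink` links two administrative record streams that share only a
participant identifier: ED visit records carrying arrival (`A`) and
departure (`D`) timestamps, and admitted-episode records carrying
admission (`H`) and separation (`S`) timestamps. The method is
deterministic and temporal: a visit and an episode of the same participant
are a *candidate* link, and the candidate is classifiable when the four
timestamps satisfy one of six pre-specified relationships (L1–L6, see
`?link_config`). Classification is first-match-wins along a precedence
order, then candidates are pruned to a one-to-one matching greedily by
shortest `|H − A|`.

Minute resolution is essential: in a frequent-presenter cohort the same
person can present several times in one day, so a date-only join is
one-to-many. All timestamps are handled as timezone-naive wall-clock times
(administrative systems record local clock time), truncated — never
rounded — to the minute.

### Why this precedence order

The six definitions are not mutually exclusive as raw predicates: a pair
with `A < H` and `S < D` satisfies both the "inside the stay" (L3) and the
"nested" (L4) conditions, and `H = A` also satisfies `A ≤ H < D`. The
package fixes the order **L1, L2, L4, L3, L5, L6** with first-match-wins:
equalities are claimed only by L1/L2, strict nesting by L4, and the
remainder of the in-stay region by L3. Under this order the six labels
partition every classifiable timestamp quadruple — the property the
per-category counts rely on — and the test suite asserts exclusivity and
exhaustiveness on randomised quadruples. Whether L4 should outrank L3 is
not decidable from the category descriptions alone; the choice here is the
one that makes "admission and discharge both inside the ED stay" a
distinguishable event rather than a subset silently absorbed by L3.

### Windows and boundaries

Both lag windows — L5 (admission after ED departure) and L6 (admission
before ED arrival) — default to 24 h and are *inclusive*
(`0 < lag ≤ 1440` min), matching the usual "≤ 24 h" reporting convention.
L6 additionally requires `A < S`: an admission that both starts and ends
before the ED arrival cannot plausibly be the same care event. No
analogous constraint is needed for L5 beyond the type invariant `H ≤ S`.
Widening either window can only add classifiable candidates, never remove
them; `window_sensitivity()` tabulates that monotone relationship, because
the choice of window trades sensitivity (more true links, especially
planned direct admissions) against specificity (capturing unrelated
re-presentations) and should be made per research question.

### Greedy shortest-lag pruning

Duplicate joins are resolved by sorting classified candidates on
(`|H − A|`, `visit_id`, `episode_id`) and accepting each pair whose two
endpoints are still free. This is deliberately *not* a globally optimal
assignment: the rule in the field is "keep the matched records with the
shortest absolute time difference", which is a greedy rule, and the id
tie-break merely makes it deterministic. The test suite checks the greedy
engine against an independently written exhaustive-iteration oracle on
instances up to 6 visits × 6 episodes.

## Continuous episodes of care

One hospital stay can generate several episode records when the patient
moves between care types or campuses before discharge. `chain_episodes()`
reassembles them: within a participant, an episode continues the open
chain iff the chain's last episode has a *planned-transfer* separation
mode (statistical separation, or separation and transfer to another
hospital) and its admission falls within the 24-h chain window after the
anchor timestamp. Requiring the planned-transfer code is what keeps
failed discharges and unplanned re-admissions within 24 h out of chains.

The anchor is configurable and defaults to the **predecessor's
separation** time. "Within 24 h of an index admission" could also be read
as anchored on the admission time; separation is chosen because a
statistical separation is an instantaneous care-type change (the next
episode starts when the previous one ends) and an inter-hospital transfer
follows the close of the prior episode, so the separation-anchored window
measures the actual handover gap. Three data-quality situations are
reported rather than raised: unmapped separation codes (treated as
non-transfer), planned transfers whose successor never arrives in the
window (dangling transfers, left as chain termini and counted), and
overlapping episodes inside a chain (permitted — same-hospital statistical
separations may share timestamps — but listed).

By default, linking happens **after** chaining (`link_after_chaining`):
continuation episodes are removed from candidate generation so an ED visit
can only link to an index admission. A continuation's admission timestamp
reflects an internal transfer, not an arrival from ED; allowing it to
capture a visit would misdate the pathway. The flat two-table join is
available by switching the flag off.

## Cleaning rules

Ingestion assembles timestamps and applies, in order: (1) records with an
unparseable date are dropped and itemised; (2) a missing clock time is
imputed as midnight and flagged (default) or dropped (strict) — flagged
imputation keeps the record available for the join while marking its
uncertainty; (3) an end-before-start record whose end, advanced by one
day, yields a duration in (0, 24 h] is treated as a midnight date-entry
slip (the encounter crossed the date change but both fields were keyed
with the start date), repaired and flagged as modified; (4) any remaining
end-before-start record is dropped by default. The alternative
`unrepairable = "flag"` retains such records, at the cost of the ordering
invariant on retained data; the default favours the invariant, which the
linkage preconditions assume. Every rule emits `(record, rule, action)`
entries in a `cleaning_report` whose counts reconcile exactly with the
retained table.

## The synthetic cohort generator

`simulate_cohort()` emulates a de-identified frequent-presenter extract
with planted ground truth. Defaults (all tunable in `sim_config()`):

* **Cohort and window**: 500 participants over January 2008 – June 2013.
* **Visit process**: per-participant visit counts are negative binomial
  (mean 7, dispersion 1.2) — a heavy-tailed stand-in for frequent
  presenters; the true inter-visit process of such cohorts is unpublished,
  so dispersion is an explicit knob. About a fifth of eligible follow-on
  visits are placed on the same day as their predecessor to exercise the
  same-day-multiples regime.
* **Admission and categories**: each visit is admitted with probability
  0.34; the planted link category is drawn from the mix
  (17.3%, 0.6%, 67.3%, 1.8%, 3.6%, 9.4%) over L1–L6, and the episode's
  `H`, `S` are *constructed* to satisfy the drawn category's definition,
  so classification of planted pairs is exact by construction (the
  generator–engine consistency test).
* **Lags**: 90% of L6 offsets fall in (0, 11] minutes (administrative
  clock discrepancies), the rest up to 24 h; 70% of L5 offsets fall within
  2 h. ED and hospital lengths of stay are log-normal with medians 3 h and
  3 days.
* **Chains**: each stay's episode count follows
  (1654, 94, 6, 3, 1)/1758 over lengths 1–5, with planned-transfer codes
  on non-final episodes and inter-episode gaps within the 24-h window.
* **Code errors**: departure-status codes contradict the truth with
  probability 0.32 for admitted visits and 0.026 for non-admitted ones;
  admission-type codes are uncertain for 7.9% of ED-arising episodes,
  and 11.5% of direct admissions are miscoded as ED-arising. These are
  length-2 probabilities because observed error rates differ strongly by
  truth stratum; a scalar is recycled.
* **Midnight errors**: with probability 0.002, a record spanning exactly
  one midnight has its end date keyed as its start date — precisely the
  error class the cleaning repair targets, so injection followed by
  cleaning is an identity on the timestamps.
* **Direct admissions**: episodes with no ED visit are added at about
  0.58 per ED-arising admission.

### The exact-recovery guarantee

A design constraint on the generator is that, with midnight errors off and
default windows, the pipeline must recover the planted links and chain
labels *exactly* (precision = recall = 1) for any seed — otherwise test
failures would be noise. This is achieved by scheduling each participant's
encounters as blocks separated by a guard gap of just over 48 h between
any visit interval and any other block's admission time. A short
case-check shows 48 h suffices: a spurious L5 needs a foreign admission
within 24 h after a visit's departure, a spurious L6 needs one within
24 h before an arrival, and the in-stay categories need the admission
inside the visit interval itself; the guard excludes all three in both
directions. Same-day repeat presentations are generated only between
non-admitted visits, which have no episodes and therefore create no
candidate pairs. The price is that the generator does not emulate the
genuinely ambiguous regime — two admissions competing at similar lags for
one visit — so passing recovery tests say nothing about linkage *error
rates* on real data, where clinically unrelated encounters can fall inside
the windows. What they do show is that the machinery (classification,
pruning, chaining, partitioning) is faithful to its rules. The audit
cross-tabs, not recovery, are the tool for reasoning about real-data
quality.

Other simplifications relative to real extracts: arrival times are uniform
over the study window rather than seasonal or diurnal, code values are
drawn uniformly within their groups, identifiers are synthetic
Medicare-like strings with no checksum validity, and heavy-tailed visit
counts are capped at 150 per participant.

## Numerical and reporting conventions

Integer percentages are rounded half-up (`round_half_up()`), matching
administrative reporting style, and a nonzero share rounding to zero is
printed `"<1"` rather than `0`. All orderings used for determinism
(candidate sort, tie-breaks, chain processing) use radix ordering on
character keys, which is locale-independent, and serialised outputs are
byte-identical across reruns of the same inputs and configuration; the
pipeline manifest records an MD5 hash per artefact to make that checkable.
Degenerate inputs (empty tables, all-zero cross-tabs) return not-available
proportions rather than errors.

Problem sizes in the test suite are chosen to keep the full run around
half a minute: synthetic cohorts of 25–500 participants (the 500 case is
the exact-recovery check), randomised property loops of 8–30 repetitions,
and the planted 1877-episode stay population for the chaining round trip.

## Known limitations

* The greedy shortest-lag matching can differ from a minimum-total-lag
  assignment on adversarial instances; that is faithful to the method, not
  a defect, but worth knowing when comparing against optimal-assignment
  linkage.
* Disposition-code groups default to one historical coding scheme; real
  studies should supply their own `code_maps` YAML per extract year.
* Transfers are inferred from separation codes only; no fallback inference
  from campus or diagnosis similarity is attempted when codes are missing.
* No probabilistic (score-based) linkage is provided; the method is
  deliberately rule-based and auditable.
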