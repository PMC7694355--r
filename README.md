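# tempolink

Patient-specific temporal record linkage between emergency department (ED)
visit records and hospital admission episode records.

## The problem

Administrative health databases usually store ED presentations and admitted
hospital episodes in separate systems that share no encounter-level key —
only a participant identifier. For cohorts of frequent presenters (for
example, people who inject drugs), the same person can have several hospital
contacts in one day, so date-only joins are ambiguous and linkage must use
full date-*time* stamps. `tempolink` implements a deterministic,
rule-based method for this setting, aimed at health-services researchers
reconstructing patient pathways from ED and admitted-episode extracts:

1. **Assemble and clean.** Combined date-time variables are built from the
   separate date and clock-time columns of each extract (minute
   resolution). Illogical records are repaired where the error pattern is
   recognisable — notably end-before-start records consistent with a
   midnight date-entry slip, which are advanced one day — and dropped
   otherwise, with every action itemised in a cleaning report.
2. **Chain.** Sequential admissions belonging to one total hospital stay
   are identified: an episode continues its predecessor's chain iff the
   predecessor's separation mode indicates a *planned* transfer of care
   (statistical separation or transfer to another hospital) and its
   admission falls within 24 h of the predecessor's separation. This keeps
   unplanned re-presentations within 24 h out of the chain.
3. **Link.** Every within-participant (visit, episode) combination is
   formed and classified against six temporal criteria relating ED arrival
   `A` / departure `D` to hospital admission `H` / separation `S`,
   first-match-wins:

   | Category | Definition |
   |---|---|
   | L1 | `H = A` (admission time equal to ED arrival) |
   | L2 | `H = D` (admission time equal to ED departure) |
   | L4 | `A < H` and `S < D` (admission and discharge inside the ED stay) |
   | L3 | `A < H < D` (admission within the ED stay) |
   | L5 | `0 < H − D ≤ 24 h` (admission after ED departure) |
   | L6 | `0 < A − H ≤ 24 h` and `A < S` (admission before ED arrival) |

   Classified candidates are pruned to a one-to-one matching greedily by
   shortest `|H − A|` (ties broken by record id, so runs are
   deterministic). By default continuation episodes found in step 2 are
   excluded from candidate generation, so visits link to index admissions
   only.
4. **Audit.** Linkage is cross-checked against what the stand-alone
   disposition codes *expected*: ED departure-status codes versus links
   found, and hospital admission-type codes versus preceding visits found,
   plus category histograms, lag distributions and window-sensitivity
   tables.

Because real extracts of this kind are protected, the package ships a
synthetic frequent-presenter cohort generator (`simulate_cohort()`) with
planted ground truth — heavy-tailed visit rates, same-day repeat
presentations, transfer chains up to five episodes, disposition-code
misclassification and midnight date errors — so every stage is testable
end to end, and `evaluate_recovery()` scores precision/recall of link and
chain recovery against the planted truth.

## Worked example

Using the small synthetic extract bundled with the package:

```r
library(tempolink)
visits_file   <- system.file("extdata", "synthetic_visits.csv",   package = "tempolink")
episodes_file <- system.file("extdata", "synthetic_episodes.csv", package = "tempolink")

v <- validate_and_clean(read_visits(visits_file)$records, "visits")
e <- validate_and_clean(read_episodes(episodes_file)$records, "episodes")
res <- link_records(v$records, e$records)
res
#> Temporal record linkage result
#>   ED visits:          30 (13 linked, 17 unlinked)
#>   Hospital episodes:  27 (13 linked, 14 unlinked)
#>   Episode chains:     24 (continuations excluded from linking)
#>   Link categories:
#>     L1:    5 (38%)
#>     L2:    0 (0%)
#>     L3:    7 (54%)
#>     L4:    0 (0%)
#>     L5:    0 (0%)
#>     L6:    1 (8%)
```

Thirteen of the 30 ED visits link to an admission; most links have the
admission timestamp at or inside the ED stay (L1/L3), and one admission was
time-stamped a few minutes *before* ED arrival (L6) — the administrative
quirk the L6 rule exists for. The audit compares these links with what the
ED departure-status codes claimed:

```r
departure_status_crosstab(res)
#> Expected versus found links
#>                        Link found No link Total
#> Admission expected             10       0    10
#> Admission not expected          3      17    20
#> Total                          13      17    30
#>   Agreement among linked records:   77%
#>   Agreement among unlinked records: 100%
```

Here 77% of linked visits carried a departure-status code that predicted
the admission — the remaining 23% would be missed entirely by research
relying on the ED table alone, which is the method's central point.
`summary(res)` adds the complete-dataset count
(visits + episodes − links = 44 combined records), per-category lag
statistics, and chain counts; `run_pipeline()` executes
read → clean → chain → link → audit in one call and writes all artefacts
plus an MD5-hashed `manifest.json` into an output directory.

A shell entry point wrapping the same functions lives at
`system.file("cli", "tempolink.R", package = "tempolink")` with subcommands
`run`, `link`, `chain`, `audit` and `simulate`.

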