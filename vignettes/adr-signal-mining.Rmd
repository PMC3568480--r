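---
title: "Mining adverse-drug-reaction signals from spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse-drug-reaction signals from spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrmine)
```

## The problem and the data model

Spontaneous reporting systems (such as the FDA's AERS/FAERS) collect
voluntary post-marketing reports. Each report carries demographic
attributes, an *unordered set* of suspected drugs and an *unordered set*
of coded symptoms (MedDRA preferred terms, PTs). The many-to-many
relationship between reports and drugs/symptoms is the crux: exported
warehouse tables de-normalize a report with m drugs and k symptoms into up
to m×k rows, and naive row counting would count such a report several
times. `adrmine` therefore regroups rows into report-level records
(`read_reports()`, `as_report_set()`) by *distinct* drug and symptom values
per report id, tolerating both full cross-product and partial row sets,
and performs **all** counting at the level of distinct reports. This one
convention is what makes every downstream count reproducible from the
de-normalized file regardless of how the export was materialized.

Missing demographic values receive the reserved token `` `r missing_token()` ``:
an ordinary category for counting, but excluded from rule antecedents
unless `include_missing = TRUE`, since "Age is unrecorded" is not a
reportable stratum.

## Disproportionality measures

Signal detection asks whether drug (set) D and symptom s are co-reported
more often than expected, quantified on the 2×2 table with cells
a (D and s), b (D only), c (s only), d (neither), conditioned on an
optional demographic constraint. The package computes PRR, ROR, the
maximum-likelihood information component IC = log₂(aN/((a+b)(a+c))), the
Yates continuity-corrected χ², and leverage a/N − ((a+b)/N)((a+c)/N).
IC here is deliberately the plain observed/expected log-ratio, not a
Bayesian shrinkage posterior; shrinkage estimators (BCPNN, gamma-Poisson)
are out of scope.

Three numerical choices deserve explanation:

* **Zero-cell policy for PRR.** With a small stratum it is common that no
  comparator report carries the symptom (c = 0), making PRR infinite. The
  default policy substitutes the background *rate* by `0.5/(c+d+0.5)` — a
  half-count continuity correction applied only where the quantity is
  undefined. For the six-report example's table (3, 0, 0, 1) this yields
  PRR = 3, the value a practitioner would quote for that table.
  Alternatives are selectable: `"haldane"` (add 0.5 to every cell) and
  `"strict"` (report an infinite, flagged value; the miners then drop the
  candidate with a message rather than erroring).
* **The signal band.** The conventional criterion is written
  "PRR − 1.96·δ > 1" with δ the standard error of ln PRR,
  √(1/a − 1/(a+b) + 1/c − 1/(c+d)). Two readings exist: the literal
  natural-scale inequality, and the log-scale convention
  exp(ln PRR − 1.96 δ) > 1. The package defaults to the **literal
  natural-scale reading** — it is the form in which the criterion is
  usually printed, and it is the only reading under which the worked
  example's (3, 0, 0, 1) rule qualifies as a signal (3 − 1.96·1 = 1.04 > 1,
  with δ's undefined 1/c term taking the same half-count as the value) —
  while `ci_scale = "log"` switches to the stricter log-scale convention.
  The same choice applies to ROR. Analysts comparing against modern
  pharmacovigilance software should use `"log"`; the default favours
  agreement with the printed form of the criterion.
* **χ² continuity clamp.** The Yates term N/2 is clamped at |ad − bc| so
  near-independence tables give 0 rather than a spurious positive
  statistic; this matches `stats::chisq.test(correct = TRUE)` (which clamps
  per-cell at |O − E|), and the test suite cross-checks the two on random
  tables.

The MHRA composite (PRR ≥ 2 ∧ a ≥ 3 ∧ χ² ≥ 4) and the universal case-count
gate a ≥ `min_count` (default 3, the field's customary minimum) are applied
by `evaluate_criterion()` and by both miners.

## The cube-based miner (single drug → symptom)

`run_cbm_ss()` executes four phases: (1) build the count cube over the
query's attributes plus Drug and PT on the time-filtered reports; (2)
generate one candidate per cell in which **every selected attribute is
concrete** (unselected attributes are marginalized with `*`; drug and PT
are always concrete) and a ≥ min_count; (3) assemble each candidate's
contingency from positive-item counts only — negative items (`all other
drugs`) are never counted directly — and score it; (4) rank the rules that
pass the measure's criterion by value, ties broken by larger a, then
lexicographic antecedent (the printed method states no tie rule; a
deterministic one is needed for reproducible top-k prefixes).

Rules in which a selected attribute would be `*` are *not* emitted as
coarser candidates: selecting an attribute asserts that the antecedent must
contain it. Margin cells remain queryable through `cube_count()`.

The cube materializes only the dimensions named by the query, with margins
evaluated lazily against the report-level pair table; nothing like a full
2ⁿ cuboid lattice is precomputed, and each query recomputes its cube. At
warehouse sizes where that matters, the offline/online split of the
multidrug miner is the intended remedy.

## The associative-classification miner (multiple drugs → symptom)

Atomic cube cells cannot express "contains both d1 and d3", so multidrug
signals use transaction mining. The **offline** stage
(`build_transactions()`) removes items and symptoms with report-level
support below min_count (every component of a reportable signal must itself
be frequent, by the a-priori principle), orders items by decreasing
support, and drops reports with no frequent symptom left. Equal-support
items are ordered by schema attribute precedence (Year, Age, Gender,
Weight, Country, then Drug), then by value — the simplest total order
consistent with frequency ordering. The result is query-independent and
serializable (`write_transactions()`), which is the point: the expensive
scan happens once, and interactive queries replay against the cache.

The **online** stage prunes per query (demographic items of unselected
attributes go; drug items always stay; transactions retaining no selected
attribute item, or no label, are eliminated), inserts the ordered
transactions into a CR-tree whose leaves count symptom labels per path, and
grows patterns from conditional pattern bases, least-frequent suffix item
first. The pattern contract is exact: every (itemset, symptom, n) with
n ≥ min_count transactions containing the itemset and labeled with the
symptom — the test suite holds the tree path to an exhaustive
subset-enumeration oracle. A report with several frequent symptoms becomes
one transaction with a label set, counted once per (transaction, label).

Two semantic points matter for correctness:

* **Final contingencies use the full warehouse.** The reduced transaction
  set drops infrequent-symptom reports, but those reports still belong in
  the stratum counts (cell d). Scoring a pattern therefore recomputes its
  2×2 table over the complete (time-filtered) report set, with the
  pattern's demographic items as the constraint and its drug set as the
  exposure. On the packaged six-report example this is visible in d = 1:
  the Age = a2 stratum contains a report whose only symptom is infrequent,
  which the reduced transactions no longer contain.
* **Emission filters.** Patterns must contain at least one item of *each*
  selected attribute and at least `min_drugs` drugs (default 2 in
  drug-interaction mode, 1 otherwise); bare-symptom patterns are never
  emitted. Ranking is by measure value, then antecedent size (larger drug
  combinations first among ties).

## The synthetic report generator

`generate_reports()` emulates the star-schema structure of a spontaneous
reporting warehouse: independent categorical demographics, independent
Bernoulli drug inclusion, and symptom inclusion with probability
p_s · Πρ over injected associations whose drug set is contained in the
report's drugs (and whose demographic stratum, when given, matches), capped
at 1. Empty drug/symptom groups are resampled so every report is valid.
Risk acts multiplicatively on the symptom probability, which keeps the
implied PRR of an injected pair analytically predictable (≈ ρ for rare
symptoms) and makes recovery tests sharp. Generation is vectorized and
fully determined by the config's seed; the global RNG state is restored
afterwards.

Defaults in the packaged example config — a 20-ish drug vocabulary with
per-report inclusion around 0.05–0.15, symptom background rates of 0.02–0.1,
and risk multipliers of 5 or more for injected pairs — mirror the sparsity
of real spontaneous data at desk scale. What the generator deliberately
does **not** emulate: stimulated-reporting waves, duplicate reports,
structured missingness, and correlated co-prescription. Passing recovery
tests therefore demonstrate the machinery is correct under the stated
generative model, not that the measures overcome real-world reporting
biases.

Problem sizes used by the validation suite: the packaged six-report
warehouse for exact worked-example checks; 50 random warehouses of 30–200
reports against brute-force oracles; 100 seeded replicates of 20,000
reports (21 drugs, 10 symptoms, one injected pair with ρ = 5) for signal
recovery, where the injected pair must rank first by PRR in at least 95%
of replicates.

## Degenerate inputs and edge behaviour

Empty input files yield empty report sets, not errors; empty candidate or
pattern sets yield empty, well-typed signal tables. A report id whose rows
disagree on a demographic value is an integrity error (silent "first row
wins" would corrupt stratum counts). Values outside all binning intervals
fall into the open-ended boundary bins `~e1` / `ek~`; binning is
idempotent on already-binned labels. `a = 0` makes IC undefined — reported
as a flagged non-signal rather than −Inf. Transactions violating the
global item order are an integrity error, since prefix sharing in the
CR-tree silently miscounts otherwise.

## Known limitations

* Per-query cube recomputation is O(reports × dims); there is no
  persistent OLAP store.
* No shrinkage or multiple-testing control across the emitted signal list;
  ranked lists from small strata carry the usual false-discovery caveats,
  and the natural-scale default band is anti-conservative for small counts
  (see above for the rationale and the `ci_scale = "log"` alternative).
* Raw quarterly AERS/FAERS exports ($-delimited, MedDRA versioning,
  deduplication) are not parsed; inputs are assumed already de-normalized
  to the supported dialect.
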