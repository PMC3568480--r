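# adrmine

Signal mining for adverse drug reactions (ADRs) in spontaneous reporting
data, for pharmacovigilance analysts and methods researchers working with
AERS/FAERS-style report collections.

Spontaneous reporting systems collect post-marketing reports in which one
patient record links to *several* drugs and *several* symptoms (MedDRA
preferred terms, PTs). `adrmine` detects disproportionately co-reported
drug–symptom combinations, optionally stratified by demographic attributes
(Year, Age, Gender, Weight, Country), with two complementary miners:

* **CBM-SS** (cube-based mining, single drug → single symptom): builds a
  report-level count cube over the selected attributes plus Drug and PT,
  derives each rule's 2×2 contingency table from positive-item counts only
  (`a = count(p, d, s)`, `b = count(p, d) − a`, `c = count(p, s) − a`,
  `d = count(p) − a − b − c`), scores it, and ranks the signals.
* **ACM-MS** (associative-classification mining, multiple drugs → single
  symptom): reduces reports to frequency-ordered transactions with symptom
  class labels (offline, cacheable), prunes them per query, inserts them
  into a CR-tree (a prefix tree with symptom counts at the leaves), and
  grows frequent drug-set patterns FP-growth style before scoring them on
  the full warehouse.

For a 2×2 table with cells *a, b, c, d* (N = a+b+c+d) the measures are

* PRR = (a/(a+b)) / (c/(c+d)), signal when PRR − 1.96·δ > 1
  (δ = SE of ln PRR),
* ROR = ad/bc (Haldane +0.5 correction when any cell is 0), signal when
  ROR − 1.96·δ > 1,
* IC = log₂( aN / ((a+b)(a+c)) ), signal when IC > 0,
* MHRA composite: PRR ≥ 2 **and** a ≥ 3 **and** Yates χ² ≥ 4,
* leverage = a/N − ((a+b)/N)((a+c)/N),

each gated by the minimum case count a ≥ 3. When c = 0 the PRR background
rate is replaced by 0.5/(c+d+0.5) (configurable; see the methods vignette).

## Worked example

The packaged six-report warehouse (`inst/extdata/table5.csv`) is small
enough to verify by hand:

```r
library(adrmine)
reports <- read_reports(system.file("extdata", "table5.csv", package = "adrmine"))

run_cbm_ss(reports, query_spec("single-drug", attributes = "Age",
                               measure = "PRR", min_count = 3)) |> tidy()
#> # A tibble: 2 × 12
#>    rank Age   drugs symptom     a     b     c     d measure value lower_bound is_signal
#>   <int> <chr> <chr> <chr>   <int> <int> <int> <int> <chr>   <dbl>       <dbl> <lgl>
#> 1     1 a2    d1    s1          3     0     0     1 PRR         3        1.04 TRUE
#> 2     2 a2    d3    s1          3     0     0     1 PRR         3        1.04 TRUE

run_acm_ms(reports, query_spec("drug-interaction", attributes = "Age",
                               measure = "PRR", min_count = 3)) |> tidy()
#> # A tibble: 1 × 12
#>    rank Age   drugs symptom     a     b     c     d measure value lower_bound is_signal
#>   <int> <chr> <chr> <chr>   <int> <int> <int> <int> <chr>   <dbl>       <dbl> <lgl>
#> 1     1 a2    d1;d3 s1          3     0     0     1 PRR         3        1.04 TRUE
```

Reading the single-drug rows: among the four reports with Age = a2, all
three that mention d1 also report symptom s1 (a = 3, b = 0), no other
report in the stratum has s1 (c = 0), and one report has neither (d = 1),
so the symptom rate under the drug (3/3) is three times the corrected
background rate — PRR = 3, above the signal band. The interaction run finds
the same three reports share the drug *pair* {d1, d3}, a two-drug signal a
single-drug cube cannot express.

Synthetic data with known ground truth (for validation studies):

```r
cfg <- read_sim_config(system.file("extdata", "sim-example.json", package = "adrmine"))
reports <- generate_reports(cfg)   # deterministic given cfg$seed
```

A shell interface wrapping the same functions ships in
`inst/scripts/adrmine` (subcommands `single-drug`, `drug-interaction`,
`transform`, `simulate`; see `?cli_main`).

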