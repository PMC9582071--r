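# mrioverlap

Quantitative analysis of two obstacles to automated MRI protocoling, for
radiology-informatics researchers and imaging-workflow analysts:

1. **How much does the ICD-10-coded admitting diagnosis constrain the protocol
   choice?** For every pair of protocols in a body region, the package
   computes the overlap coefficient of their admitting-diagnosis sets, plus a
   *complement* overlap of each protocol against all the others combined. High
   overlap means the diagnosis alone cannot separate the protocols.
2. **How heterogeneous are scanner protocol trees, and how much of that is
   just naming?** The package compares trees across scanners at raw
   sequence-name, standardized sequence-name and protocol-name level, where
   standardized names are derived deterministically from acquisition
   parameters (TR, TE, TI, technique, orientation, ...) by a configurable rule
   engine — never from the free-text name a site typed in.

At its core are the set-similarity statistics, for finite sets A and B:

    J(A, B)  = |A ∩ B| / |A ∪ B|            (Jaccard index)
    oc(A, B) = |A ∩ B| / min(|A|, |B|)      (overlap coefficient)

with elements of the diagnosis sets being whole per-exam *code combinations*
(an exam coded `M54.2;M50.30` contributes the single element `M50.30+M54.2`),
and the complement overlap of protocol A defined as oc(A, C) with C the union
of every other protocol's element set. Multi-label statistics (cardinality,
density, diversity), a "performed more than five times" protocol-frequency
filter, and a chi-square variability test on raw-vs-standardized name counts
round out the toolkit. A fully seeded synthetic generator produces exam logs
and multi-scanner protocol trees with the statistical structure the analyses
assume — skewed protocol frequencies, Zipf-like code popularity, planted
pairwise overlaps realized exactly, naming-synonym noise over a shared
parameter core — so everything is testable without clinical data.

## Worked example

```r
library(mrioverlap)

cfg <- read_synthetic_config(system.file("configs", "toy.yaml", package = "mrioverlap"))
log <- generate_exam_log(cfg)            # 120 spine exams, 6 protocols
res <- run_dx_overlap(log, "spine", min_count = 6)
print(res)
#> Admitting-diagnosis overlap, region 'spine' (codeset elements)
#>   6 protocols retained (>= 6 exams), 0 excluded, 0 empty-code exams
#>   pairwise oc range: 0.00-0.62; complement oc range: 0.28-0.78
#> Exams: 120
#> Unique ICD-10 codes: 28
#> Label cardinality: 1.2
#> Label density: 0.04
#> Label diversity (code sets): 56
```

The complement range 0.28–0.78 says every protocol's diagnosis profile recurs
substantially under other protocols: on this log, no protocol could be
selected from the admitting diagnosis alone. The toy config plants an overlap
of exactly 0.5 between its first two protocols, and the pipeline recovers it
exactly:

```r
planted <- attr(log, "planted")
res$matrix$values[planted$protocol_i, planted$protocol_j]
#> [1] 0.5
```

Tree comparison on the matching synthetic trees:

```r
trees <- generate_trees(cfg)
compare_trees(trees, "scanner-1")
#> Protocol-tree comparison (reference: scanner-1)
#>  scanner_id site_id n_raw_names n_standardized_names n_protocol_names oc_raw
#>   scanner-1  site-A          56                   24               20     NA
#>   scanner-2  site-A          56                   24               20  0.643
#>   scanner-3  site-B          53                   24               20  0.547
#>  oc_standardized oc_protocol
#>               NA          NA
#>            1.000         0.8
#>            0.875         0.8
#> Means: 20 protocols, 55 raw sequence names, 24 standardized
#> Raw-vs-standardized variability: X^2 = 0.034, df = 2, p = 0.983
```

Raw sequence names overlap at 0.64/0.55 across scanners; after rule-based
standardization the overlap rises to 1.00/0.88 — most of the apparent
cross-scanner difference was spelling, not acquisition content. Matrices
export with `write_matrix_csv()` (two-decimal cells, terminal `complement`
column); the standardization rules live in `inst/rules/default.yaml` and can
be replaced per site.

## Analysis workflow

The full study runs as numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R       # study-scale exam log + 3 scanner trees
Rscript analysis/02_dx_overlap.R     # per-region overlap matrices + label stats
Rscript analysis/03_standardize.R    # standardized trees, unique-name counts
Rscript analysis/04_compare_trees.R  # cross-scanner report + chi-square block
```

Each writes its tables and a run manifest under `results/`. The methods
vignette (`vignettes/overlap-methods.Rmd`) documents the statistics, the rule
table, the generator's design and its limitations.

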