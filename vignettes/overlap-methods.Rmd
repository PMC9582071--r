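---
title: "Measuring diagnosis-protocol overlap and protocol-tree heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diagnosis-protocol overlap and protocol-tree heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrioverlap)
```

## The problem

Protocoling — choosing the right MRI protocol for an ordered exam — depends on
the clinical indication, and the ICD-10-coded admitting diagnosis is the only
structured proxy for that indication most radiology information systems carry.
Two quantitative questions decide whether automated protocoling built on the
admitting diagnosis can work, and whether a model trained at one scanner can
transfer to another:

1. **How separable are protocols by admitting diagnosis?** If the same
   diagnosis combinations recur under many protocols, the diagnosis alone
   cannot drive the protocol decision.
2. **How heterogeneous are scanner protocol trees?** If two scanners describe
   largely the same acquisitions under different sequence names, a model keyed
   to names will not transfer — and rule-based sequence-name standardization
   should recover the hidden agreement.

This package implements both analyses over exam-log CSVs and protocol-tree
JSON documents, and ships a seeded synthetic generator so the full pipeline is
testable and demonstrable without access to clinical data.

## Set-similarity statistics

For finite sets $A$ and $B$ the package provides the Jaccard index

$$J(A,B) = \frac{|A \cap B|}{|A \cup B|}$$

and the overlap (Szymkiewicz–Simpson) coefficient

$$oc(A,B) = \frac{|A \cap B|}{\min(|A|, |B|)},$$

with $J(A,B) \le oc(A,B)$ always, and $oc = 1$ whenever one set contains the
other. The overlap coefficient is the primary statistic: admitting-diagnosis
sets of different protocols are small and of very different sizes, and a rare
protocol whose few diagnoses all recur under a frequent protocol should score
1, not the small Jaccard value its size imbalance would produce.

**Elements are code combinations.** The unit element of the diagnosis sets is
the whole combination of ICD-10 codes attached to one exam
(`code_set_element()`: sorted, deduplicated, joined canonically), not the
individual code. Two exams coded `M54.2` and `M54.2+M50.30` contribute two
distinct elements. A per-code granularity is available
(`run_dx_overlap(..., granularity = "code")`) as a documented variant, off by
default.

**Complement overlap.** For protocol $A$ the complement overlap is
$oc(A, C)$ where $C$ is the union of every *other* protocol's element set in
the filtered dataset. The literal set-theoretic complement
$A^c = \{x \in U \mid x \notin A\}$ would be disjoint from $A$ by
construction, making $oc(A, A^c)$ identically zero and the statistic
uninformative; the union-of-others reading is the one under which the
coefficient measures what it is used for — whether a protocol's diagnosis
profile is unique to it — and the only reading consistent with reported
nonzero complement values. A dataset containing a single protocol has an empty
complement; the coefficient is then an explicit undefined marker (`NA`), never
a silent 0 or 1.

**Multi-label statistics.** `label_statistics()` reports label *cardinality*
(mean codes per exam), *density* (cardinality divided by the number of unique
codes; by construction `density * n_unique_codes == cardinality` exactly) and
*diversity* (number of distinct code combinations). Exams with an empty code
set carry no label information; they are excluded from the statistics and from
element construction, always with a logged count, never silently.

## The diagnosis-overlap pipeline

`run_dx_overlap()` composes, for one body region:

1. `build_elements()` — exact lowercase-tag region match, empty-code exclusion
   with count, one element per exam into its protocol's set;
2. `filter_protocols()` — drop protocols performed fewer than `min_count`
   times (default 6, i.e. *more than five*; rarer protocols give degenerate
   one- or two-element sets whose overlap is mostly noise);
3. `pairwise_matrix()` — the symmetric matrix with unit diagonal plus the
   complement column;
4. `label_statistics()` — computed over **all** region exams with codes,
   *before* the frequency filter. Dataset-level label summaries describe the
   log as collected, while the matrix describes the analyzable protocol
   subset; mixing the two denominators would understate the label space.

Label order in the matrix is descending exam count with lexicographic
tie-breaks — explicit, deterministic and configurable
(`label_order = "alphabetical"`), so results are invariant to input row
order. Values are kept at full precision internally; rounding to two decimals
happens only in `write_matrix_csv()` (fixed format: label column, one column
per protocol, terminal `complement` column, undefined complement as an empty
cell).

## Sequence-name standardization

Scanner operators name sequences freely (`t1_se_sag`, `T1 SAGITTAL`, ...), so
raw names are site habits, not acquisition facts. `standardize_sequence()`
derives a name purely from acquisition parameters; the raw name is never
consulted, so permuting raw names provably cannot change any output.

The weighting classifier is an ordered first-match-wins rule table,
externalized to YAML (`rules/default.yaml`) so a site can replace it without
touching code:

| order | rule | condition | token |
|---|---|---|---|
| 1 | diffusion | any b-value > 50 s/mm² | `DWI` |
| 2 | flair | IR with TI in [1800, 2800] ms | `FLAIR` |
| 3 | stir | IR with TI in [120, 300] ms | `STIR` |
| 4 | t1-spin-echo | SE/TSE, TR < 800 ms, TE < 30 ms | `T1` |
| 5 | t2 | TR > 2000 ms, TE > 80 ms | `T2` |
| 6 | proton-density | TR > 2000 ms, TE < 30 ms | `PD` |
| 7 | t1-gradient-echo | GRE, flip > 50°, TR < 800 ms | `T1` |
| 8 | catch-all | — | `OTHER` |

The ordering is load-bearing: diffusion EPI has long-TR/long-TE values that
would read as T2, and FLAIR's TR/TE alone are T2-like — placing diffusion
before inversion recovery before relaxation rules resolves both ambiguities.
The TI windows are wide enough to cover 1.5 T and 3 T conventions; the rule
file validator enforces well-formed intervals and a terminal catch-all so
classification is total. These rules are this package's own
literature-conventional contrast heuristic; they are the component a site is
most likely to want to tune, which is why they live in data, not code.

Token assembly is fixed: weighting, technique family, orientation,
dimensionality, fat-saturation marker, post-contrast marker — e.g.
`"T1 SE SAG 2D"`, `"FLAIR TSE TRA 2D FS"` — with `UNKNOWN` tokens omitted and
the `2D/3D` and `POST` tokens togglable (whether a standardized vocabulary
should distinguish 3D variants or contrast phases is a site policy question;
both switches default to on).

## Cross-scanner tree comparison

`compare_trees()` reports, per scanner, the unique raw-name, standardized-name
and protocol-name counts; for every non-reference scanner the overlap
coefficient against the reference at each level; count means across scanners
(full precision, plus a display integer rounded half away from zero, so a mean
of 310/3 displays as 103); and a chi-square test on the 2×K table of raw vs
standardized counts across the K scanners (homogeneity construction, expected
counts from margins, df = K−1).

**Chi-square caveat.** This construction tests whether the raw/standardized
count *ratio* varies across scanners, not whether standardization reduces
counts overall. On count tables where every scanner shrinks by a similar
factor the rows are near-proportional and the statistic is close to zero —
the test then (correctly) reports that the reduction is homogeneous, which
should not be read as "no significant reduction". A goodness-of-fit test of
the raw vs standardized totals would address the reduction itself but
conflates scanners; the package exposes the homogeneity construction and
leaves the totals comparison to the reader. An all-pairs overlap mode
(`all_pairs = TRUE`) supplements the reference-scanner convention.

## The synthetic generator

`generate_exam_log()` and `generate_trees()` emulate the *statistical*
structure the analyses consume — never clinical semantics (no claim that a
given code warrants a given protocol).

Study-scale defaults (one six-month, three-scanner, two-site practice
extract): spine 727 exams, 127-code vocabulary, code-set size distribution
{1: 0.9, 2: 0.1} (mean cardinality 1.1), protocol frequencies heavy-tailed in
[6, 341] over 18 protocols; brain/head 249 exams, 98 codes, {1: 0.8, 2: 0.2}
(mean 1.2), frequencies in [6, 120] over 16 protocols. Code popularity is
Zipf-like with exponent 1.2, chosen so single-code occurrence spans roughly 1
to ~200 at spine scale; the span is an envelope property, not a hard
assertion. Trees default to 100 protocols per scanner over a shared core of
110 acquisition-parameter tuples, two spellings per tuple, synonym-noise rate
0.5 and site-specific tuple rate 0.15, which yields roughly 200 raw sequence
names per scanner collapsing to ~75 standardized names, and a same-site
versus cross-site raw-overlap gradient (≈0.85 vs ≈0.76).

Design choices worth knowing:

* **Planted overlaps are constructed, not sampled.** For a configured
  `(i, j, target)` pair the two protocols' element sets are built from a
  reserved vocabulary slice: `target × min(|A_i|, |A_j|)` shared combinations
  plus private ones, disjoint per pair. The smaller protocol's frequency is
  nudged down to the nearest size at which the target is exactly realizable
  (freed exams move to unplanted protocols), so pipeline recovery is an exact
  equality test, not a statistical one. Infeasible targets are rejected
  naming the pair.
* **Synonym pools are disjoint per parameter tuple** (the tuple id is embedded
  in each spelling, as sites commonly number their sequences), so raw names
  always refine parameter tuples and the standardized-name count can never
  exceed the raw count on generator output.
* **Every pool tuple is used at least once per scanner**, so a configuration
  with zero synonym noise and no site-specific tuples yields identical
  raw-name sets on all scanners (overlap exactly 1) — the degenerate anchor
  the directional tests build on.
* **One root seed, per-component streams.** Each component (vocabulary,
  frequencies, names, each scanner's tree) draws from its own deterministically
  derived stream, so outputs are byte-reproducible and adding a component does
  not perturb the others.

What the generator does **not** emulate: code-protocol clinical plausibility,
per-protocol code-set size distributions beyond the global cardinality mix,
vendor-specific naming grammars, and the breadth of a real standardized-name
vocabulary (the generator's archetype space collapses to ~75 standardized
names where a real 3 T catalog sustains closer to 100). Passing tests
therefore demonstrate the correctness and the directional behavior of the
statistics — not that any particular clinical dataset will show a given
overlap value. At brain/head scale the realized unique-code count falls below
the 98-code vocabulary (Zipf tail codes go undrawn in 249 exams), so the
realized label density rounds to 0.02 rather than 0.01; the spine-scale
envelope (cardinality 1.1 ± 0.05, density printing as 0.01) is the one the
test suite pins.

## Numerical and degenerate-input conventions

* Overlap and Jaccard reject empty inputs where their denominators would be
  zero; the complement coefficient returns a distinguished `NA` for a
  single-protocol dataset.
* ICD-10 codes are canonicalized (case, whitespace, dot insertion after the
  third character) and treated as opaque strings; no catalog validation, since
  coding-year drift would invalidate historical logs.
* A set TI without an inversion-recovery flag is rejected; diffusion b-values
  with a stated non-EPI technique warn only, because vendor logs are
  inconsistent about diffusion readouts.
* Matrix CSVs render exactly two decimals; every in-memory value keeps full
  precision. Count-mean display values round half away from zero.
* Problem sizes in the shipped tests and drivers are the study-scale defaults
  above (≈1000 exams, 3 trees of 100 protocols); property suites use 100-200
  randomized instances of up to 10 protocols × 50 elements, where the naive
  double-loop oracle is exact and fast.

## Workflow

The `analysis/` drivers run the whole study in order: `01_simulate.R`
(dataset), `02_dx_overlap.R` (per-region matrices and label statistics),
`03_standardize.R` (standardized trees and count reduction),
`04_compare_trees.R` (cross-scanner report with the chi-square block). Each
writes its tables under `results/` together with a run manifest (command,
parameters, seed, package version, timestamp) so any output can be
regenerated byte-identically.
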