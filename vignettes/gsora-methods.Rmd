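---
title: "Methods: over-representation analysis with gsora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: over-representation analysis with gsora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsora)
```

## The model

`gsora` performs over-representation analysis (ORA): given a query gene
list (typically a differential-expression hit list), a collection of
predefined gene sets, and a reference background, it asks for each set
whether the query overlaps it more than a random draw would. This is the
overlap-counting flavor of "gene set enrichment analysis" used by
web-based plant annotation servers, distinct from rank-based GSEA — there
is no ranking statistic and no permutation walk, only a 2×2 table per
set.

For one gene set, all counts are taken *within the background*:

* $N$ — background size (whole genome or a user-supplied list),
* $n$ — query genes present in the background,
* $K$ — set genes present in the background,
* $k$ — genes in query ∩ set ∩ background.

Under the null hypothesis that the query is an exchangeable draw from the
background, $k \sim \mathrm{Hypergeometric}(N, K, n)$, and the
over-representation p-value is the upper tail

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

Three tests are offered:

* **Hypergeometric / one-sided Fisher** (the default). These are the same
  statistic — with both margins fixed, Fisher's exact test conditions on
  the hypergeometric distribution — and the package documents and tests
  this identity rather than pretending they differ. The tail is computed
  by summing exact log point-probabilities (`lchoose`) with a
  log-sum-exp guard; no normal approximation is ever used.
* **Two-sided Fisher**, summing all tables (same margins) whose point
  probability does not exceed the observed one, with a $1 + 10^{-7}$
  relative tie tolerance. Off by default: enrichment tools look for
  over-representation, and a depletion-sensitive two-sided test only
  dilutes power; it is provided for completeness.
* **Pearson χ²** with 1 df on the cells $(k,\, n-k,\, K-k,\, N-n-K+k)$,
  Yates-corrected by default. It is an asymptotic approximation: with any
  expected cell below 5 the result carries a `small_expected` flag, and
  in the far tail (adjusted p below ~$10^{-4}$) it can differ from the
  exact tail by orders of magnitude — our own enumeration shows the
  halved Yates p tracks the exact tail within ~10% only in the moderate
  regime (p ≈ 0.05–0.3). It exists because users coming from contingency
  table workflows expect it; the exact test is always the better choice.

Genes outside the background are silently excluded from every count but
never silently lost: the query audit reports the raw count, the
non-redundant count and the dropped IDs, mirroring the ID-redundancy
report a user sees before any statistics.

## Multiple testing

Collections carry hundreds to tens of thousands of sets, so raw p-values
are adjusted across the family of tested sets. Six procedures are
exposed (`adjust_p()`, delegating to `stats::p.adjust`): Bonferroni,
Holm, Hochberg, Hommel, Benjamini–Hochberg (BH) and Benjamini–Yekutieli
(BY). **BY is the default**, paired with the one-sided Fisher test: gene
sets overlap heavily (GO ancestors contain their descendants wholesale),
so FDR control valid under arbitrary dependence is the defensible
choice; BH is the universal companion for users willing to assume
positive dependence.

The family is, by default, *all* sets tested in the run, pooled across
the selected categories — one query, one family. A per-category mode
(`adjust_results(per_category = TRUE)`) is available for per-category
displays, where each category is its own family; pooled adjustment is
the default because it is the more conservative reading and matches the
single summary table the tool emits.

Significance selection (`select_significant()`) uses adjusted p <
cutoff, default 0.05, sorted ascending with ties broken by larger
overlap then name so output order is total and reproducible.

## Gene-set collections and categories

Sets are organized in four categories: `GO`, `GeneFamily`, `Curated`,
`Motif`. GMT (Broad dialect: name, description, members) is the
interchange format; per-set provenance (author, PubMed ID, source
database, URL) travels in a sidecar TSV rather than overloading the GMT
description field, keeping GMT files consumable by any GSEA-style tool.
Curated literature-derived sets follow the `AUTHOR_DESCRIPTION[_UP|_DN]`
naming convention (`make_curated_name()`), with non-alphanumeric runs
collapsed to single underscores.

IDs are case-sensitive and whitespace-stripped; plant locus identifiers
carry case-significant suffixes, so no case folding is ever applied
silently. Transcript-model suffixes (`.1`) are kept verbatim.

## Ontology propagation

GO/PO annotation files record *direct* annotations; the true-path rule
says a gene annotated to a term is implicitly annotated to every
ancestor. `propagate_annotations()` materializes this: each term's set is
the union of direct annotations over the term and its descendants,
computed in one topological sweep (children before parents) over the
`is_a` and `part_of` edges. Other relationship types (e.g. `regulates`)
are ignored with a warning — propagating them would violate the
true-path conventions. Namespaces never mix because ontology roots are
disjoint; no cross-namespace edges exist in the inputs we accept.

Two invariants follow and are tested: set size is monotone along every
child→parent edge, and each root's set equals all genes annotated in its
namespace.

For visualization, `enriched_subgraph()` induces the subgraph of
significant terms plus all ancestors (so every enriched term appears in
context), and `render_dot()` emits Graphviz DOT with nodes filled by
adjusted-p bin. Default bins are $\{10^{-10}, 10^{-5}, 0.01, 0.05\}$ on
a four-step ramp — a conventional spacing covering the dynamic range of
typical results; the bin edges are configurable because no single
convention exists. DOT text, not a rendered image, is the artifact:
invoking a layout engine is the user's concern, and text output keeps
runs byte-comparable.

## ID conversion

`convert_ids()`/`query_to_locus()` translate among locus, symbol and
probe-set identifiers through a user-supplied TSV. Relations are
many-to-many; a probe expanding to several loci contributes *all* of
them, because picking a "best" locus would silently bias $K$ and $k$.
The expansion is recorded in the audit so the user can see how much of
their locus-space query is probe fan-out. Probe detection
(`_at`-suffix) is advisory only; a declared `--id-type` always wins, and
mixed-looking input without a declaration is an error rather than a
guess.

## The synthetic-data generator

Every stage is testable without downloads via seeded generators
(`sim_config()`, `make_collection()`, `make_query()`, `make_dag()`,
`make_mapping()`). The default configuration is the package's reference
study condition: a 5,000-gene universe, 200 sets of 20–100 genes
(uniform sizes, categories round-robin), and a 150-gene query with
signal fraction 0.5 — half the query drawn from one planted set, half
uniform background noise. This emulates the shape of a real use case — a
~150-gene stress-response up-regulated list carrying one strong
biological signal — at a scale where an exhaustive run takes
milliseconds.

Design choices worth recording:

* **One named RNG stream per generator**, derived from the single config
  seed; adding a generator can never perturb another's output, and the
  caller's RNG state is always restored.
* **Planted-set feasibility.** The signal portion is sampled from the
  planted sets' union without replacement, so the union must be at least
  as large as the signal portion. The generator draws planted sets
  uniformly and rejects infeasible draws (so the choice is uniform over
  feasible ones); a configuration with no feasible choice at all is a
  hard error. Under the defaults this means the planted set is a set of
  ≥75 genes.
* What the simulation does **not** emulate: correlated set membership
  (real GO sets are nested), annotation bias toward well-studied genes,
  and realistic ID vocabularies. Tests passing on these fixtures
  demonstrate algorithmic correctness and calibration under the stated
  null, not robustness to the dependence structure of real collections —
  which is exactly why BY is the default adjustment.

## Numerical choices and degenerate inputs

* Tail sums run in log space with a log-sum-exp guard; $k = 0$ (or $k$
  at the lower support bound) returns exactly 1.
* Sets with zero overlap are retained in the full result table with
  p = 1 — the annotation table must stay complete — but never appear in
  the significant selection.
* Adjusted p of exactly 0 (possible only through underflow) is floored
  at $10^{-300}$ for the $-\log_{10}$ bar-chart transform.
* Set-size filters default to min 2 / no upper bound: permissive on
  purpose, configurable per run.
* An empty query∩background is an error with an actionable message (it
  almost always means the wrong ID type or background), not an empty
  result.
* χ² with a zero margin is an error (statistic undefined), not NA.

## Problem sizes used in validation

The test suite validates the exact tests exhaustively over all 2×2
tables with $N \le 30$ (~40,000 tables) against brute-force pmf
summation at $10^{-12}$; the six corrections against independent
step-up/step-down implementations (plus explicit closed-testing Simes
for Hommel at small family sizes, and an external reference
implementation at full length); null calibration with 1,000 uniform
queries of 100 genes against 200 sets in a 5,000-gene universe; and
planted-set recovery across 100 seeded simulations at the reference
condition, requiring BY-significance and rank one in at least 95. These
sizes give the calibration checks standard errors of ~$5\times10^{-4}$
on the null exceedance fraction while keeping a full run comfortably on
one CPU.

## Limitations

* ORA treats genes as exchangeable: no gene-length, expression-level or
  annotation-bias correction (tools in the goseq family address this).
* The χ² option is an approximation retained for familiarity; it should
  not be used for small sets.
* Curated content is the user's to supply; the package ships formats,
  statistics and generators, not a species resource.
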