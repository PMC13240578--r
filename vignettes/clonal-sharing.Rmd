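---
title: "Cross-compartment clonal sharing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-compartment clonal sharing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoshare)
```

## Scope and model

`clonoshare` analyses paired single-cell expression and receptor-contig data
from subjects sampled in three compartments: lung tissue (interstitium),
bronchoalveolar lavage fluid (BALF) and peripheral blood (PBMC). The working
model is that a clonotype — all cells sharing the same rearranged receptor
chains — marks a migration history: the set of compartments in which a clone
is detected tells where its cells have been. The package takes cluster
labels, compartments and groups as *inputs*; it performs no integration,
embedding or clustering of its own.

A clone's **occupancy** is a triple of booleans (lung, PBMC, BALF), each
true when the clone has at least `min_cells` cells there. Expanded clones
(size ≥ `min_size` within subject, all compartments pooled) are classified:

* lung ∧ ¬PBMC ∧ BALF → **P1A** (interstitium-to-airway sharing),
* lung ∧ ¬PBMC ∧ ¬BALF → **P1B** (lung-resident only),
* lung ∧ PBMC ∧ ¬BALF → **P2** (blood–interstitium sharing),
* any other non-empty occupancy → **OTHER**,
* empty occupancy or failed expansion gate → **UNCLASSIFIED**.

We deliberately implement the pattern assignment as a *rule-based total
function* of occupancy rather than as hierarchical clustering of abundance
profiles. A clustering-derived assignment depends on dendrogram cutting and
is not reproducible from a table of definitions; the rule-based mapping is
auditable, idempotent, and exhaustively testable over all eight occupancy
states. The four occupancy states outside the three named patterns
(BALF-only, PBMC-only, PBMC+BALF, triple-positive) are kept as an explicit
`OTHER` class instead of being forced into the nearest pattern, so
pattern prevalences are never inflated by residual states.

### Assumptions

* Clone identity is subject-scoped by construction: the same chains in two
  subjects are two clones. Public clones are out of scope.
* Cells are exchangeable within a clone; detection of a compartment is
  binarised by `min_cells` (default 1 — no detection floor beyond presence;
  the data the package targets have no printed floor to inherit).
* The expansion gate defaults to `min_size = 2` (any clone seen more than
  once). "Highly expanded" analyses can raise it; the threshold is a
  parameter, not a claim.

## Entropy indices

All indices use natural logarithms and the convention 0·ln 0 = 0.

* **Expansion index** of a stratum with clone frequency vector *p* over *N*
  clones: `1 − H(p)/ln N`; 0 for all-singleton strata, 1 for a monoclonal
  stratum. A single-clone stratum is defined as 1 if that clone has ≥ 2
  cells, else 0 (the formula's 0/0 corner).
* **Migration index** of a cluster: each clone's cells in the cluster define
  a distribution *q* over compartments; the index is Σ *w H(q)* with *w* the
  clone's share of the stratum's cells. For a pairwise call, cells are first
  restricted to the two compartments (clones absent from both drop out);
  this makes pairwise values invariant to deleting the third compartment,
  which the tests assert.
* **Transition index**: the same machinery over phenotype-cluster
  distributions.

Normalised variants divide by ln *K* (*K* = number of categories
considered), so a clone split evenly between two compartments scores exactly
1; when only one category is considered the normalised index is defined as 0
(no sharing is possible). Raw (unnormalised) variants are available via
`normalize = FALSE` since plotted index scales in the literature are often
unit-free and ambiguous.

**Aggregation across subjects.** Indices are computed per subject, then
averaged weighted by the subject's stratum cell count. Because clone
namespaces are subject-scoped, this weighted mean is algebraically identical
to a pooled computation over all cells — the test suite asserts the identity
rather than assuming it. The per-subject formulation is kept as the
definition because it makes the subject the unit of analysis, consistent
with the composition statistics (where *n* always refers to subjects, never
cells).

## QC and expression statistics

Low-quality cells are those with mitochondrial fraction **strictly above
0.10** or **fewer than 200** detected genes. Both bounds are read literally
("over", "less than"), so boundary cells (exactly 10% mito, exactly 200
genes) are kept; both are configurable in `qc_thresholds()`.

Normalisation is library-size scaling to `scale = 1e4` followed by
`log1p`. Differential expression uses the two-sided Wilcoxon rank-sum test
per gene — chosen as the single default because the field's conventional
toolkits apply several tests interchangeably and the rank-sum test is the
least parametric of them — with Benjamini–Hochberg correction applied
*within* each contrast. Composition tests across groups are likewise BH
corrected within each family of cell types. A gene with identical values in
all cells gets *p* = 1 and zero log-fold-change by convention. Signature
scores are plain means of normalised expression over the signature's genes
present in the matrix; the MHC-I-style score is shipped as a configurable
signature with no default gene list claimed.

## Reference scoring with fine-tuning

To infer the functional state of unlabelled (e.g. control-lung) cells, the
package builds **pattern-level pseudo-bulk references** from labelled cells:
per-gene medians of normalised expression (median rather than mean for
robustness to dropout; configurable). For every ordered pattern pair (A, B)
the `genes_per_pair = 50` genes with the largest *strictly positive*
difference profile(A) − profile(B) are marker genes; constant genes can
therefore never be selected.

A query cell's score for a pattern is the Spearman correlation (mid-ranks
for ties) between its normalised expression and the pattern's profile over
the union of all marker genes present in the query (minimum 20 genes).
Rank correlation makes scores invariant under any strictly monotone
transform of the query's values, which the tests assert directly.

**Fine-tuning** retains the patterns scoring within `margin = 0.05` of the
top, re-scores using only the markers that discriminate among the retained
patterns, and repeats until a single pattern remains or the retained set
stops shrinking. On a stall the highest-scoring retained pattern wins (ties
broken by initial score, then lexicographically, with a logged count); if
the retained patterns are exactly tied — as with duplicated reference
profiles, where no discriminating marker exists — the cell is labelled
`AMBIGUOUS` and flagged `pruned`. Termination is guaranteed because the
retained set never grows.

Prediction is **per cell**, not per cluster: averaging before scoring would
hide mixed clusters, and the per-cell scores are what the downstream
summaries and heatmaps consume.

## The synthetic cohort generator

The generator is first-class, tested code: it emits exactly the dialects the
readers parse (10x contig CSV or AIRR TSV, Matrix Market counts with
feature/barcode sidecars, metadata TSV) plus a JSON truth file, and the same
seed yields byte-identical files.

What it emulates:

* **Clonal expansion**: clone sizes follow a geometric (or Zipf) law with a
  configurable expanded fraction (default 0.5 of clones have size ≥ 2,
  geometric *p* = 0.4 — small clones dominate, as in real repertoires).
* **Pattern-structured occupancy**: each clone draws a pattern from
  `pattern_mix` (default 0.5/0.2/0.3/0 over P1A/P1B/P2/OTHER) and allocates
  its cells over the pattern's allowed compartments by a
  Dirichlet–multinomial. With `enforce_occupancy = TRUE` (default) every
  allowed compartment of an expanded clone receives at least one cell, so
  the configured pattern *is* the realised occupancy (occupancy
  probabilities 0/1). A pure multinomial would leave small clones
  mono-compartment with high probability, conflating allocation noise with
  classification error; the guarantee separates the two so that
  classification accuracy and proportion recovery are each testable on
  their own. Disabling the guarantee restores fully stochastic occupancy.
* **Phenotype programs**: marker counts are negative binomial
  (variance μ + φμ², φ = 0.3) with multiplicative 2^effect shifts — resident
  markers (ITGAE, CXCR6, CXCR3), cytotoxic/cycling (GZMB, GNLY, MKI67) for
  the activated cross-compartment pattern, circulating markers (CX3CR1,
  FGFBP2, KLRG1) for the blood-derived pattern. Default effects are 2
  (4-fold). Background genes draw log-normal baseline means (median 5,
  sdlog 1.2) shared across patterns, giving the rank structure of a real
  transcriptome; without it, rank correlations between single cells and any
  profile hover near zero and carry no signal.
* **QC covariates**: beta-distributed mitochondrial fractions and log-normal
  gene counts, with a configurable fraction (default 2%) of deliberately
  low-quality cells that the QC stage should remove.
* **BCR mode**: heavy/light chains with clone-level isotypes drawn from
  `isotype_mix`.

What it does **not** emulate: batch effects, ambient RNA, doublets,
cell-type-specific library sizes, somatic hypermutation, or any dynamic
(velocity-like) structure. Passing recovery tests on these cohorts
demonstrates the pipeline's correctness under its own model, not robustness
to artefacts of real data.

## Numerical and design choices

* Strict inequalities at both QC boundaries (literal reading; configurable).
* Probability vectors are validated to sum to 1 within 1e-9; index-oracle
  agreement is asserted to 1e-12.
* Doublet-chain handling: a barcode with more than two productive chains of
  one locus keeps the two with most UMIs (standard practice; ties broken
  deterministically by CDR3 and gene names).
* Duplicate gene symbols are disambiguated in file order (`X`, `X.1`, ...).
* Clone-identity policy is exposed (`NT_VJ` default, matching vendor
  clonotype semantics for the targeted data; `AA_VJ`, `RAW_ID` selectable)
  because the upstream convention is not fixed by the data formats
  themselves.
* Expansion is judged on the clone's total size across compartments, not per
  compartment — cross-compartment sharing analysis would otherwise exclude
  exactly the clones it studies.
* Per-subject expansion (clone namespaces are subject-scoped) is the only
  coherent reading for multi-subject cohorts and is used throughout.

## Problem sizes

The test suite and the acceptance script run on cohorts of 5 pneumonia
(plus 0–2 control) subjects × 200 clones (~2 200–3 100 cells, ~110 genes),
100-table random-oracle sweeps with up to 50 clones, and a 10 000-clone
draw for the clone-size law goodness-of-fit. These sizes give stable
recovery statistics (binomial/multinomial standard errors of a few percent)
while keeping the whole suite fast.

## Known limitations

* The pattern rules assume three compartments; other designs (e.g. missing
  BALF in controls) yield `OTHER`/`UNCLASSIFIED` rather than adapted rules —
  reference scoring is the supported route for such groups.
* Reference scoring degrades when pattern programs overlap heavily or
  marker effects are weak; with few informative genes among the pairwise
  markers, rank correlation cannot separate a resting resident cell from an
  activated one whose extra markers happen to be noisy. The recovery tests
  therefore state their effect sizes explicitly.
* Entropy indices are biased downward in tiny strata (few clones); no
  small-sample correction or bootstrap interval is implemented.
* `evaluate_against_truth` requires that the analysed cohort and the truth
  file describe the same simulation (matched barcodes); it stops on
  mismatch rather than guessing.
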