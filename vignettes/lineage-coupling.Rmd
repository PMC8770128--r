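---
title: "Clone calling and lineage coupling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone calling and lineage coupling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecall)
```

This vignette is the package's account of its science: what the clone-calling
procedures and the lineage-coupling statistic assume, what every tunable
parameter does and why its default is what it is, what the synthetic-data
generators do and do not emulate, and where the design was genuinely open and
a choice had to be made.

## The measurement problem

A lineage barcode is a synthetic sequence delivered to a progenitor cell and
inherited by its descendants; because it is transcribed, droplet scRNA-seq
reads it out alongside the transcriptome. Two designs are supported:

* a **combinatorial lentiviral barcode**: three fragments, each from a pool
  of 500 distinct 14-nt sequences, concatenated with a constant per-library
  *viral index*. One integration per cell; all cells of a clone carry the
  identical combination (500³ = 125 million possibilities).
* a **transposon integration barcode**: a 37-nt sequence of random positions
  bridged by fixed nucleotides, with *multiple* genomic integrations per
  cell. All cells of a clone carry the identical *set* of integrations, and
  clones are recognised by set overlap rather than identity of a single
  sequence.

Raw reads are noisy: PCR duplicates inflate counts, UMIs acquire
single-substitution errors, barcode fragments acquire one or two
substitutions, and ambient or chimeric molecules attach spurious barcodes to
cells. Every threshold below exists to make clone membership robust to these
processes.

## Combinatorial clone calling

Processing per read: cut the payload at fixed offsets into three fragments
and the index; align each fragment to its pool; drop the read if any
fragment is unmatched or ambiguous or the index is not an exact known index.
Then collapse UMIs per (cell, barcode), and per cell decide a clonal
barcode.

Parameters (`sticr_params()`):

| parameter | default | role |
|---|---|---|
| `max_fragment_mismatch` | 2 | Hamming tolerance of fragment alignment |
| `umi_collapse_mismatch` | 1 | UMI error collapse radius |
| `min_umi_candidate` | 5 UMIs | candidacy threshold per cell–barcode pair |
| `dominance_factor` | 5× | fold-excess defining a dominant barcode |
| `min_umi_final` | 9 UMIs | retention threshold for any clonal call |

The pools are built (and, for synthetic libraries, generated) with a minimum
pairwise Hamming distance of 5 within each pool, so a 2-mismatch alignment
can never be ambiguous between intact fragments; ambiguity only arises for
heavily damaged reads, which are discarded. Alignment is an exhaustive
Hamming scan over the ≤ 500-entry pool — deterministic, index-free, and
exactly the contract the mismatch bound states. Exact matches are resolved
by hashing first, so the scan only touches reads that contain errors.

UMI collapse is *directional*: UMIs are visited in order of decreasing read
support (lexicographic on ties) and a UMI merges into the first surviving
UMI within the collapse radius, else survives. This absorbs the typical
error pattern — a low-count satellite one substitution away from a
high-count parent — without transitively chaining distant UMIs together; a
chain A–B–C at pairwise distance 1 keeps two survivors when C is two
substitutions from A. The collapse never increases counts.

The tier rule mirrors the two ways a cell can be confidently clonal:
exactly one barcode passes candidacy (tier 1), or several pass but the top
one has at least `dominance_factor` times the UMIs of the runner-up
(tier 2, the "dominant" barcode). Either way the call must reach
`min_umi_final` distinct UMIs. Clonal analyses default to tier 1 only
(`build_clone_table(tier_policy = "tier1_only")`); tier 2 is admitted
explicitly where a study accepts dominant barcodes. One open point in the
tier semantics: when only one barcode passes candidacy but a sub-threshold
runner-up exists, we grant tier 1 without a dominance comparison — the
candidacy threshold already declared the runner-up noise. The alternative
(requiring dominance against sub-threshold competitors too) is stricter;
flagged as a sensitivity knob rather than silently chosen.

Barcodes observed in two or more datasets cannot be clonal marks (separate
animals cannot share a clone) and indicate a library collision or index
contamination; they are blacklisted and their cells dropped. Clone ids are
formed as `dataset:barcode`, which makes cross-dataset collisions
structurally impossible to miss.

## Integration clone calling

Parameters (`tracker_params()`): barcodes shorter than 37 nt are discarded;
a (cell, UMI, barcode) triple needs ≥ 10 reads; a (cell, barcode) pair needs
≥ 6 distinct UMIs (exact UMIs — no mismatch allowance here, where UMI
diversity is high and the read threshold already removes most noise). The
surviving pairs form a binary cells × barcodes matrix; cells are clustered
by `1 − Jaccard` distance with average linkage and the tree is cut at
0.999.

The cut height deserves a note. A height of 0.999 is only coherent on a
distance scale bounded by 1: cells with entirely disjoint integration sets
sit at exactly distance 1 and can never merge below the cut, so clones are
unions of cells that share at least part of their integration sets. We
therefore apply the cut on the `1 − Jaccard` merge heights (recorded in the
output's `cut` attribute). Cutting a raw unnormalised dendrogram instead
would make the threshold depend on dataset size, which cannot be the
intended semantics.

An optional Hamming-≤3 pre-collapse of barcode sequences
(`barcode_collapse_mismatch`) exists but is off by default: sequence-level
clustering of transposon barcodes belongs to library QC, not to per-dataset
clone calling, and collapsing real distinct barcodes would merge clones.

## The lineage coupling statistic

For a clone `c` with `n` cells and a state pair `{s1, s2}`: `k` is the
number of its cells in either state; `c` is *shared* if `k ≥ 2` with at
least one cell in each state (equivalently: at least one in each — `k ≥ 2`
then follows); `p = k/n`; the pair's metric is `M = Σ_shared p`. Weighting
by `p` lets a clone fully captured by the pair count more than one barely
touching it.

The null shuffles the state assignments of individual cells, preserving the
per-state totals exactly — a permutation, not a resample. The shuffling unit
is the cell, not the clone: clones fragment under the null, which is
precisely the "no lineage structure" hypothesis being tested. One global
shuffle per iteration serves all pairs, so the per-pair null values are
correlated across pairs exactly as the observed metrics are. With `N =
10,000` iterations (the default), `z = (M_obs − mean)/sd` with the
population standard deviation over the `N` values (at this `N` the n vs
n−1 distinction is immaterial; the choice is recorded here). Pairs with a
degenerate null (sd = 0, e.g. all clones singletons) report z = 0 and are
flagged rather than propagating NaN.

Implementation note: because a clone is shared exactly when both states are
present, the full pair matrix is `X + t(X)` with `X = t(C/n) A`, where `C`
is the clones × states count matrix and `A = (C > 0)`. Each permutation is
one `tabulate` and one small matrix product, which is what makes 10,000
iterations take under a second at typical sizes.

The coupling correlation of two states is the Pearson correlation of their
z-score vectors against all *other* states: the diagonal and the pair's own
entry are excluded, since including the shared coordinate would correlate
every pair with itself. ("All the z-scores" without exclusions is the other
reading; the exclusion is recorded in the result metadata.) With `S` states
this leaves `S − 2` coordinates, so correlations are only informative for
`S ≥ 5`; at `S = 4` they are ±1 by construction, and at `S ≤ 3` they are
reported as 0 with an `undefined` flag. Lineage dendrograms are
average-linkage trees on Euclidean distances between correlation rows.

Clone composition uses two categorisations with exact threshold semantics:
purity is `"100%"` iff the dominant class fraction equals 1, `">80%"` iff
it lies strictly between 0.8 and 1, `"<80%"` otherwise (a fraction of
exactly 0.8 is `"<80%"`); lineage is glia-only / neuron-only / mixed over
the glial classes (astrocyte, OPC, oligodendrocyte) and neurons, with
clones containing neither (vascular, epithelial, ...) held out as `other`
and excluded from the three-way denominators.

## Barcode collisions

Two progenitors receiving the same barcode fuse into one apparent clone.
With library abundances `p_i` and `n` labelled cells, the expected number
of distinct barcodes is `Σ_i (1 − (1 − p_i)^n)`; collisions are `n` minus
that. The Monte-Carlo simulation (`simulate_collisions()`, default 20,000
replicates over population sizes 10¹–10⁶) exists to propagate *abundance
skew* measured from a real library, for which the closed form is the exact
expectation and serves as the built-in cross-check. The uniform closed form
is evaluated via `log1p`/`expm1` so it remains accurate at library sizes of
10⁸. For the largest populations the replicate count is scaled down to a
draw budget and flagged `scaled_down`, with the Monte-Carlo standard error
reported so the precision loss is visible. Any skew lowers the expected
unique count relative to uniform (the function is Schur-concave in the
abundances), which is why modelling measured abundances matters.

The library size itself (e.g. an extrapolated 6–7 × 10⁷ distinct barcodes)
is an *input*; saturation-curve extrapolation is out of scope.

## Developmental mapping

Postnatal cell-type model vectors are per-cluster means of log-normalized
expression over a supplied shared variable-gene list (gene selection is an
input, not a step). Each embryonic cell is assigned to the model vector
with the highest Pearson correlation; ties break to the first cluster in
declared order and are flagged; zero-variance cells are flagged unmapped.

Significance is empirical: the model vectors stay fixed and the single-cell
expression is permuted 100 times; for each permutation and cell the largest
correlation to any model is recorded, and `p` is the fraction of permuted
maxima *strictly* larger than the observed best correlation — no
pseudocount, so `p = 0` occurs, deliberately, at 100 permutations. The
permutation unit is ambiguous in principle; the default shuffles each
cell's values across genes (preserving the cell's expression distribution,
the natural null for a correlation against fixed vectors), and
within-gene-across-cells shuffling is available as `scheme =
"within_gene"`; results carry the scheme used. BH-adjusted FDR < 0.1
(strict) gates which cells count as mapped. Cluster-level structure uses
`1 − Spearman` distances between average expression vectors, with constant
vectors flagged rather than silently dropped.

## What the synthetic generators emulate — and what they do not

`gen_barcode_library()` enforces the ≥ 5 pairwise Hamming separation within
pools (so mismatch-tolerant alignment is well-posed by construction) and
offers log-normal abundance skew as a product of per-fragment weights.
`gen_clonal_population()` plants the ground truth: clone sizes from a
constant/truncated-geometric/empirical spec (default truncated geometric
with mean 3, max 30 — many small clones, a tail of large ones, matching the
reported means and maxima of in vivo clone sizes), per-clone state
distributions, and per-clone barcodes or integration sets.
`gen_reads()` adds the noise the thresholds guard against: PCR duplication,
single-substitution UMI satellites (a duplicated read splits off with a
mutated UMI), ≤ 2-substitution fragment errors confined to one fragment,
and per-(cell, integration) dropout. UMI length is 10 nt and cell barcodes
16 nt, matching common droplet chemistry; the read layout concatenates
fragments at fixed offsets because extraction must be testable, and the
transposon mask defaults to 16 random positions in 37 nt (≈ 4.3 × 10⁹
combinations; the mask is a parameter and is recorded in the read-set
metadata, since the printed complexity of such libraries is
convention-dependent).

`gen_expression_pair()` generates matched embryonic/postnatal matrices
directly on the log-normalized scale: per-gene baselines, disjoint marker
sets elevated by `effect` in matched clusters, Gaussian noise, clamped at
zero. Defaults (500 genes, 20 markers/cluster, effect 2, noise 0.5, 100
cells/cluster, 5 matched cluster pairs) put mapping accuracy near 1 while
leaving the null regimes reachable: `effect = 0` gives chance-level
assignment, and `effect = 0` with a flat baseline (`baseline_range =
c(1, 1)`) gives exchangeable pure-noise cells under which empirical
p-values are uniform. Note the distinction: with a *variable* baseline and
no effect, cells still correlate strongly with every model vector through
the shared gene profile — assignments are at chance but p-values are small.
That is a property of correlation mapping on real data too, and is why the
method's specificity comes from the FDR gate plus the *relative* best
correlation, not from raw p-values.

The generators do **not** emulate: transcriptome reads or alignment (the
expression matrices are born normalized), ambient RNA and doublets,
chimeric PCR between barcodes, batch effects, or cluster-assignment error
in the annotations. Passing recovery tests on this synthetic data therefore
demonstrates the correctness of the pipeline's logic and thresholds, not
robustness to every artefact of real libraries.

## Numerical and degenerate-input choices

* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical seeds give identical results to the byte.
* Hamming comparisons are byte-wise on fixed-length strings; length
  mismatches are errors, never silent non-matches.
* `cutree`-style flat cuts, `hclust(method = "average")` and `dist` are the
  clustering substrate; flat partitions agree with a literal O(n³) UPGMA
  oracle in the tests.
* Degenerate cases return flagged values, not errors, where the quantity is
  well-defined (sd = 0 nulls → z = 0 flagged; constant vectors → 0 or NA
  with flags; empty integration matrices → valid empty results with
  diagnostics); they error where it is not (empty clone tables, unknown
  state labels, fewer cells than states, empty state selections).
* Abundance vectors must sum to 1 within 1e−9.

## Problem sizes used in the tests

The shipped tests run the full pipeline at sizes chosen for a single
desktop CPU: clone-recovery at ~350 cells over 100 clones against the full
500³ library; null calibration and planted-signal detection at 500 cells,
100 clones, 8 states with 1,000 permutations per replicate and 50
replicates; exhaustive-permutation oracles at 8 cells (70 arrangements);
collision curves at 2,000 replicates up to n = 10⁴. The defaults users see
(`n_perm = 10000`, 20,000 collision replicates, populations to 10⁶) are the
full-scale settings; the implementation is fast enough that the coupling
default runs in under a second at these sizes.

## Known limitations

* Tier semantics with sub-threshold competitors (above) are a convention.
* The 0.999 cut interpretation is on the Jaccard distance scale (above).
* Coupling correlations need ≥ 5 states to be informative.
* The collision model is pre-sequencing: it ignores recovery efficiency
  and dropout after labelling.
* Mapping assumes the supplied gene list is shared and the matrices are
  already log-normalized; no normalisation is performed.
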