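---
title: "Stage-specific expression, biclustering and gene duplication: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific expression, biclustering and gene duplication: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devodup)
```

## The scientific question

In nematodes such as *Pristionchus pacificus*, a developmental timecourse of
bulk transcriptomes (early larvae, stress-resistant dauer larvae, late larvae
and adults) raises two linked questions:

1. Which genes are *developmentally regulated* — coherently up- or
   down-regulated in particular subsets of stage comparisons — and which are
   *housekeeping* genes, robustly expressed and never differentially
   expressed?
2. How do those regulated genes relate to the gene-duplication history of the
   genome? Specifically, are genes with lineage-specific paralogs
   over-represented among the regulated genes, as expected if duplications of
   developmentally deployed genes were repeatedly retained on the focal
   lineage?

`devodup` implements the complete computational chain for this analysis:
pairwise differential-expression (DE) calls discretized into a ternary
matrix, sign-consistent biclustering of that matrix, an inparalog-aware
reciprocal-best-hit (RBH) orthology classification of the focal proteome
into five classes, exact hypergeometric enrichment tests, and
phylogeny–expression association. A simulator generates two-species gene
families with known ground truth so every stage of the pipeline can be
validated without external data.

## The ternary DE matrix

Expression arrives as a non-negative gene × sample matrix (FPKM-like units;
the pipeline is unit-agnostic beyond non-negativity). For $m$ samples, every
ordered pair $(i, j)$ with $i < j$ in column order is a *comparison*; ten
samples give the canonical $\binom{10}{2} = 45$ comparisons. The caller in
`call_pairwise_de()` is deliberately transparent plumbing:

$$x_{gc} = \begin{cases} +1 & \log_2\frac{e_{gj}+c}{e_{gi}+c} \ge \tau \\
-1 & \log_2\frac{e_{gj}+c}{e_{gi}+c} \le -\tau \\ 0 & \text{otherwise,}\end{cases}$$

with pseudocount $c = 1$ and threshold $\tau = 1$ by default, and calls
forced to 0 when the gene is below the expression floor (default 1) in both
samples. $+1$ means up in the later-listed sample; the orientation is a
package convention, stable and documented, since nothing downstream depends
on it beyond consistency (recomputing with swapped pair order flips all
signs). When a replicate-group factor is available, calls are additionally
gated by a Welch t-test on $\log_2(e + c)$ between the two groups,
Benjamini–Hochberg corrected across genes *within each comparison* at FDR
0.01. The caller is a pluggable boundary: any external DE engine producing
ternary calls can feed `find_biclusters()` directly.

Housekeeping genes (`housekeeping_genes()`) are genes with expression at or
above a floor (default 10) in *every* sample and an all-zero ternary row.
Developmentally regulated genes are defined as the union of all bicluster
member genes (`regulated_genes()`).

`sample_overview()` provides the standard sample-level diagnostics: Spearman
correlations of expression (constant samples flagged, their correlations
reported as missing), a PCA of samples on genes expressed above zero — in
all samples by default; the "any sample" variant is a configuration switch
because the filter is genuinely ambiguous in this kind of analysis — and
average-linkage hierarchical clustering of samples on Euclidean distances
between per-pair DE-call counts. Average linkage is a package choice; the
analysis tradition states the distance but not the linkage.

## Biclustering model

A *bicluster* is a gene subset $G$, a comparison subset $C$ and a sign
$s_c \in \{-1, +1\}$ per comparison, scored additively:

$$S(G, C, s) = \sum_{g \in G, c \in C} \begin{cases} +a & x_{gc} = s_c \\
-b & x_{gc} = 0 \\ -d & x_{gc} = -s_c, \end{cases}$$

with defaults $a = 1$, $b = 1$, $d = 2$: a mismatching call is evidence
*against* coherence and is penalized more strongly than a missing call.
This is a fixed-weight, additive analogue of the likelihood-weighted
coherent-submatrix objective of SAMBA-style biclustering; it is documented
as SAMBA-inspired, not SAMBA-identical, and full-genome bicluster counts
from analyses run with the original tool are therefore benchmarks, not
reproduction targets.

Because the optimal sign of a column for a fixed gene set is always its
majority nonzero sign (for any positive $a, d$), the package treats the sign
vector as a function of $(G, C)$ — majority sign over the current genes,
ties resolved to $+1$. This makes the score well-defined per state, removes
a class of stale-sign local optima, and coincides with setting the sign at
comparison-addition time.

`find_biclusters()` is fully deterministic:

1. **Seeds.** Every gene pair seeds a candidate with the comparisons on
   which both genes carry the same nonzero call; seeds narrower than
   `min_comparisons` are discarded.
2. **Greedy local search** (compiled, in C++): repeatedly apply the single
   best-scoring addition or removal of one gene or one comparison until no
   move improves the score. Move ties are broken by scan order (gene
   additions, gene removals, comparison additions, comparison removals,
   each in ascending index).
3. **Plateau escape.** Additive ternary scores are heavily tied, so strict
   greedy ascent can stall on plateaus. At each local optimum the search
   explores chains of score-neutral single moves (depth ≤ 6, bounded node
   budget, visited-set against cycles) and restarts the descent from the
   first strictly better state found. On every 6×6-or-smaller random
   instance we have tested, the resulting top bicluster attains the global
   optimum found by exhaustive search over all (gene subset, comparison
   subset, sign) triples; the test suite re-verifies this on 500 random
   instances.
4. **Filters.** Local optima with score ≥ `score_threshold` (default 10)
   and at least `min_genes` × `min_comparisons` cells (defaults 5 × 3) are
   kept; scanning survivors in descending score, any bicluster whose
   gene-set Jaccard similarity with an already-kept bicluster exceeds
   `max_overlap_jaccard` (default 0.75) is dropped. Reported biclusters may
   still partially overlap, which is intended: overlapping modules are part
   of the biological signal.

Raising the score threshold can only shrink the reported set (the search is
threshold-independent), which the suite checks as a nesting property.

`bicluster_stage_profile()` summarizes a bicluster's member-gene expression
per sample (median, quartiles) together with the stage-specificity
statistic below.

## Stage specificity: maximum pairwise Wilcoxon p

For a gene set and a partition of samples into stage groups,
`stage_specificity_stat()` pools the member-gene expression values of each
stage and runs a two-sided Wilcoxon rank-sum test for every pair of stages,
reporting the **maximum** p-value over pairs: a set is stage-specific only
if *every* pair of stages separates. The null distribution is exact — a
tie-aware full permutation distribution of the rank sum, computed by
dynamic programming over doubled midranks — whenever both sides have at
most 12 values, and a tie-corrected normal approximation otherwise. The
two-sided p is $\min(1,\, 2\min(P(W \le w), P(W \ge w)))$, the convention
of the exact test in base R. The exact path is validated against brute
enumeration of all group assignments up to 8 values per side.

## Orthology classification

The focal proteome is partitioned into five classes from all-vs-all protein
similarity searches (BLAST tabular input, e-value < 0.001 throughout,
following the conventional homolog-detection threshold):

* **one-to-one**: reciprocal best hits between the focal and comparison
  species, accepted only if *neither* partner has an inparalog;
* **conserved multicopy** (many-to-X): a panel hit plus membership in a
  within-species paralog family;
* **conserved singleton**: a panel hit, no paralogs;
* **orphan multicopy** / **orphan singleton**: no hit to any panel species.

Operationally:

1. `best_interspecies_scores()` gives every gene its best cross-species bit
   score (ties: smaller e-value, then lexicographic subject id). Bit score,
   not e-value, is the ranking metric because bit scores are
   database-size-independent; the underlying searches rarely make the two
   disagree.
2. `find_inparalogs()` flags gene $g$ if any same-species hit scores
   strictly above $g$'s best cross-species hit — the Inparanoid-style
   operational definition of a post-speciation duplicate. The one-sentence
   rule is directionally ambiguous in the source tradition; the package
   evaluates it directionally per gene by default and offers a symmetric
   variant (both partners must beat their own cross-species best) as a
   configuration switch.
3. `one_to_one_orthologs()` intersects reciprocal best hits with the
   inparalog veto.
4. `paralog_components()` builds the undirected within-species hit graph
   (an edge if either direction passes the threshold — the "or" reading;
   the alternative "and" reading is not exposed because thresholded BLAST
   asymmetries at e < 0.001 are rare and the connected components are
   almost always identical) and labels connected components; genes in
   components of size > 1 are multicopy.
5. `classify_genes()` applies the priority: one-to-one first; then
   conserved vs orphan by panel-hit status (genes absent from every hit
   table are orphan singletons — absence of hits is the defining
   evidence); then multicopy vs singleton with one-to-one genes *removed
   before* the subdivision, so a one-to-one gene never counts as multicopy
   and a gene whose only paralog partner is a one-to-one gene is a
   singleton.

The five classes always partition the focal gene set; the suite fuzzes this
over 100 random simulations. `evaluate_against_curated()` compares
one-to-one predictions against a manually curated table of
comparison-species genes and reports the confusion counts, with curated
genes absent from the hit universe counted separately as unassessable.

## Enrichment statistics

All enrichment and overlap tests are exact hypergeometric tails
(`hypergeom_test()`, `hypergeom_enrichment()`, `set_overlap_test()`):
upper tail for enrichment, lower tail for depletion, both computed as exact
mass sums, with the enrichment factor $(k/n)/(K/N)$ and
Benjamini–Hochberg adjustment of each tail within an analysis batch. Raw p
values are always reported alongside adjusted ones. The analysis tradition
this package follows reports DAVID-style one-sided tests without naming
them; fixing the one-sided hypergeometric (one-tailed Fisher exact) for
both directions is the package's explicit choice. The discreteness of the
hypergeometric makes null p-values conservative (stochastically larger
than uniform), which the suite checks by resampling.

`bicluster_class_enrichment()` runs the bicluster × orthology-class batch
and summarizes how many biclusters are significantly enriched for a chosen
class (default: conserved multicopy, the lineage-specific duplication
signal) at an adjusted q ≤ 0.05.

## Phylogeny and expression

`paralog_profile_correlation()` quantifies within-family expression
coherence: all pairwise Spearman correlations of member profiles, the
family median, and an empirical upper-tail p against a seeded background of
randomly paired genes from different families.

`lineage_specific_clades()` extracts the maximal clades of a gene tree
whose tips are all focal-species genes (size ≥ 2) — the subtrees created by
duplications on the focal lineage. Unrooted input is rooted at the midpoint
of the path between the two most distant non-focal tips; with a single
non-focal tip that tip becomes the outgroup, and with none the stored
orientation is kept. An explicit outgroup can always be imposed upstream by
re-rooting the tree before loading. `clade_regulation_association()` then
formalizes the visual observation that regulated genes concentrate in such
clades as a 2×2 hypergeometric association over the tree's focal tips, and
counts regulated genes among one-to-one orthologs. This association test is
an extension of the qualitative, inspection-based argument in the analysis
tradition, and is documented as such.

## The simulator: what it emulates, and what it does not

The analyses above were designed for real two-species data; the generative
model in `simulate_families()` / `simulate_similarity()` /
`simulate_expression()` is a deliberately minimal stand-in whose every
choice is configurable:

* **Families.** Each of `n_families` families carries
  $1 + \mathrm{Poisson}(\text{dup rate})$ copies per lineage; all
  duplications post-date the speciation, and gene loss is folded into
  `orphan_fraction` (families with no detectable non-focal member, default
  0.32 — roughly the orphan share observed in nematode proteome surveys).
  The realized topology determines the true orthology class of every focal
  gene.
* **Similarity.** Within a lineage, duplications branch off a trunk at
  times uniform on (0.2, 0.9) before present with the speciation at 1.0,
  giving an ultrametric caterpillar family tree; genes of different
  families sit at depth 3. Bit scores decay as $S_0 e^{-kt}$ in divergence
  time $t$ (defaults $S_0 = 500$, $k = 2$), e-values are the fixed
  monotone map $10^{-\text{bitscore}/10}$, and directed hits below a
  detectability floor (bit score 50) are omitted — under the defaults
  cross-family hits fall below the floor, like BLAST hits past the
  reporting cutoff. Only the ranks matter to the orthology rules, so any
  strictly monotone map would serve; optional log-normal score noise
  degrades those ranks smoothly.
* **Expression.** Ten samples in three ordered stage groups (early 3,
  dauer 3, late 4) by default. A regulated family draws one archetype —
  high (50) in its stage group, baseline (5) elsewhere — shared by all
  members; unregulated families are flat at 40, safely above the
  housekeeping floor of 10. Per-gene, per-sample multiplicative log-normal
  noise has `noise_sigma = 0.15` by default, chosen so that the plain
  fold-change caller's false-call probability per comparison for a flat
  gene is about $10^{-3}$ — emulating the low false-positive regime of an
  FDR-controlled DE caller at 0.01 — while archetype fold changes
  ($\log_2(51/6) \approx 3$) are called essentially always.
* **Regulation and duplication.** A family is regulated with baseline
  probability `regulated_fraction` (default 0.17, the regulated share of
  the genome in the motivating analysis); for multicopy families the odds
  are multiplied by `multicopy_regulation_boost` (default 3), planting the
  excess of multicopy genes among regulated genes that the enrichment
  stage is designed to detect. Regulation and the archetype are sampled in
  `simulate_families()`, where the realized copy number is known, so the
  truth table is complete and immutable before expression is simulated.

What the simulator does **not** model — and what passing tests therefore do
not certify about real data: sequence evolution (no alignments, no
substitution models), read-count sampling and library-size effects,
gene loss after duplication, partial or incorrect gene models, domain-level
homology (chimeric proteins), expression divergence between paralogs
(members share archetypes exactly up to noise), and any correlation between
expression level and detectability. Identical seeds and configurations give
byte-identical output, and the simulators restore the caller's RNG state.

`plant_ternary_blocks()` generates the separate planted-bicluster benchmark
(coherent blocks with configurable agreement inside sparse background),
used to measure recovery: at the benchmark setting of five 40×8 blocks with
0.9 agreement and 0.05 background in a 1000×45 matrix, recovery is asserted
at mean gene-set Jaccard ≥ 0.9 over ten seeds.

## Numerical choices and degenerate inputs

* Scores and tie-breaks in the bicluster search are compared with an
  absolute tolerance of $10^{-9}$; with integer weights all comparisons are
  exact.
* All move-order, seed-order and sign tie-breaks are lexicographic by
  index, so every pipeline stage is deterministic given its inputs.
* Wilcoxon: exact permutation null (tie-aware) up to 12 per side; the
  degenerate all-equal input returns p = 1.
* Constant samples have undefined rank correlations: they are flagged and
  reported as missing rather than silently dropped.
* Duplicate (query, subject) similarity rows collapse to the best bit
  score (then smallest e-value) — the deduplication convention across
  merged search runs.
* Genes present in the annotation universe but absent from every hit table
  are orphan singletons.
* Empty bicluster sets, families with fewer than two expressed members,
  trees without focal tips and absent lineage-specific clades all return
  explicitly flagged empty/undefined results, never errors.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen as the smallest sizes at which each property is
statistically meaningful: oracle equivalence of the bicluster search on 500
random matrices up to 6×6; planted-block recovery on 1000×45 matrices over
10 seeds; orthology truth recovery on noise-free simulations up to ~40
genes and partition fuzzing over 100 random configurations; enrichment
exactness for every universe size up to 60; the boost-detection experiment
on 500-family simulations over 20 seeds with a 20-seed null calibration.
The full-genome figures of the motivating analyses (tens of thousands of
genes, external DE and biclustering engines, pinned proteome releases) are
not reproducible from a desk and are treated as external-data benchmarks
throughout.

One power limitation is worth stating plainly: with the survey-calibrated
marginals above, a three-fold *family-level* odds boost translates into a
modest *gene-level* enrichment of conserved multicopy genes in the
regulated set (the acceptance script prints the factor and p it obtains on
each run; factors around 1.1–1.6 are typical at 400–500 families). The
direction is recovered essentially always, but single-run significance at
stringent thresholds is not guaranteed at this scale — detecting a
family-level association diluted across gene copies simply needs larger
universes than a 500-family simulation provides.
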