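# devodup

Developmental expression biclustering and gene duplication analysis.

`devodup` implements, as a tested and reusable R pipeline, the computational
chain used to link stage-specific gene expression in a nematode
developmental timecourse to the duplication history of its genome. It is
aimed at comparative genomicists and developmental biologists who have (a) a
gene × sample expression table across developmental stages, (b) all-vs-all
protein similarity hits (BLAST tabular) between a focal species and a panel
of comparison species, and optionally (c) gene trees and protein-domain
annotations — and who want to ask whether developmentally regulated genes
are enriched for lineage-specific paralogs.

## What it computes

**Ternary DE matrix.** For every ordered sample pair (i, j), i < j, a gene
is called up (+1), down (−1) or unchanged (0) by a transparent pseudocounted
log fold-change rule, optionally gated by a replicate-aware test with
Benjamini–Hochberg control within each comparison:

    x_gc = +1  if log2((e_gj + c)/(e_gi + c)) ≥ τ,   −1 if ≤ −τ,   else 0

Ten samples give the canonical 45 comparisons. Housekeeping genes are those
with expression ≥ 10 in every sample and an all-zero row.

**Biclustering.** Overlapping gene × comparison modules with a coherent sign
per comparison, scored additively (+a per matching call, −b per zero, −d per
opposite call; defaults 1/1/2) and found by a deterministic greedy local
search (compiled) from all gene-pair seeds, with plateau escape and a
Jaccard redundancy filter. Developmentally regulated genes are the union of
all bicluster members. A per-bicluster stage-specificity statistic reports
the maximum two-sided Wilcoxon rank-sum p over all pairs of stage groups,
exact (tie-aware) for small samples.

**Orthology.** The focal proteome is partitioned into five classes from
similarity hits at e-value < 0.001: one-to-one orthologs (reciprocal best
hits, accepted only if neither partner has an inparalog — an intraspecies
hit scoring above the gene's best interspecies hit), conserved multicopy
(many-to-X), conserved singleton, orphan multicopy and orphan singleton,
with paralog families as connected components of the within-species hit
graph and one-to-one genes removed before the multicopy/singleton
subdivision. Predictions can be scored against a manually curated table.

**Enrichment.** Exact hypergeometric upper/lower tails (enrichment and
depletion), enrichment factors, and BH adjustment within each batch — for
orthology classes or domain annotations within biclusters, regulated and
housekeeping sets, and for overlap tests against external gene sets.

**Phylogeny × expression.** Within-family Spearman correlation of paralog
expression profiles against a resampled cross-family background, extraction
of maximal focal-species-specific clades from gene trees (with midpoint
rooting between the most distant non-focal tips for unrooted input), and a
2×2 association between clade membership and developmental regulation.

**Synthetic data.** A two-species gene-family simulator
(birth process per lineage, ultrametric similarity scores monotone in
divergence, stage-archetype expression with log-normal noise, a planted
excess of regulation among multicopy families) provides ground truth for
every stage; a separate planted-block generator benchmarks the bicluster
search. All simulators are seeded and byte-reproducible.

## Worked example

```r
library(devodup)

cfg   <- family_sim_config(n_families = 150, seed = 42)
truth <- simulate_families(cfg)          # ground-truth families and classes
hits  <- simulate_similarity(truth)      # BLAST-tabular-like hit table
expr  <- simulate_expression(truth)      # 10-sample stage timecourse

de  <- call_pairwise_de(expr)            # genes x 45 ternary calls
bcs <- find_biclusters(de)
bcs
#> bicluster_set: 3 bicluster(s)
#>   [1] 22 genes x 21 comparisons, score 462.0
#>   [2] 21 genes x 21 comparisons, score 441.0
#>   [3] 15 genes x 24 comparisons, score 360.0

reg <- regulated_genes(bcs)
hk  <- housekeeping_genes(expr, de)
length(reg); length(hk)
#> [1] 58
#> [1] 144

res <- classify_genes(hits, orthology_config("Ppa", "Cel"),
                      genes = rownames(expr))
res
#> orthology_result: 205 focal genes, 55 one-to-one pairs
#>   conserved_multicopy      74 (36.1%)
#>   conserved_singleton      23 (11.2%)
#>   one_to_one               55 (26.8%)
#>   orphan_multicopy         25 (12.2%)
#>   orphan_singleton         28 (13.7%)

er <- hypergeom_enrichment(reg, split(res$calls$gene, res$calls$class),
                           rownames(expr))
er[er$category == "conserved_multicopy",
   c("category", "K", "n", "k", "factor", "p_enrich", "q_enrich")]
#>              category  K  n  k factor p_enrich q_enrich
#> 1 conserved_multicopy 74 58 32   1.53 0.000371  0.00185
```

The three biclusters are the three stage archetypes (early-, dauer- and
late-high); the regulated set of 58 genes is enriched 1.5-fold for conserved
multicopy genes (exact hypergeometric p ≈ 4×10⁻⁴), recovering the planted
association between developmental regulation and lineage-specific
duplication.

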