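#' Exact hypergeometric enrichment/depletion test from counts
#'
#' Tail probabilities of drawing `k` category members in a query of size `n`
#' from a universe of `N` genes of which `K` belong to the category.
#' Enrichment is the upper tail `P(X >= k)`, depletion the lower tail
#' `P(X <= k)`, both exact sums of the hypergeometric mass. The enrichment
#' factor is `(k/n) / (K/N)` (NA when `K` or `n` is 0).
#'
#' @param k overlap count.
#' @param K category size.
#' @param n query size.
#' @param N universe size.
#' @return a list with `p_enrich`, `p_deplete`, `factor` and the counts.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (N < 1) stop_devodup("empty universe")
  if (K > N || n > N)
    stop_devodup("category or query larger than the universe")
  if (k > min(K, n) || k < max(0, n + K - N))
    stop_devodup(sprintf(
      "impossible configuration: overlap %d outside [%d, %d] for K=%d, n=%d, N=%d",
      k, max(0, n + K - N), min(K, n), K, n, N))
  p_enrich <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_deplete <- phyper(k, K, N - K, n, lower.tail = TRUE)
  factor <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
  list(k = k, K = K, n = n, N = N,
       p_enrich = p_enrich, p_deplete = p_deplete, factor = factor)
}

#' Hypergeometric gene-set enrichment over a batch of categories
#'
#' Tests one query gene set against every category, with exact
#' hypergeometric tails and Benjamini-Hochberg adjustment of each tail
#' within the batch.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param categories named list of character vectors (each a subset of
#'   `universe`), e.g. orthology classes or protein-domain annotations.
#' @param universe character vector: the gene universe.
#' @param label optional label for the query set, recorded in the output.
#' @return a data frame of class `enrichment_result` with one row per
#'   category: set, category, N, K, n, k, factor, p_enrich, p_deplete,
#'   q_enrich, q_deplete.
#' @export
hypergeom_enrichment <- function(query, categories, universe, label = "query") {
  if (length(universe) == 0) stop_devodup("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop_devodup("query genes outside the universe: ",
                 paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  if (is.null(names(categories))) stop_devodup("'categories' must be a named list")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(unique(categories[[nm]]), universe)
    K <- length(cat_genes)
    k <- length(intersect(query, cat_genes))
    ht <- hypergeom_test(k, K, n, N)
    data.frame(set = label, category = nm, N = N, K = K, n = n, k = k,
               factor = ht$factor, p_enrich = ht$p_enrich,
               p_deplete = ht$p_deplete, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_enrich <- p.adjust(out$p_enrich, "BH")
  out$q_deplete <- p.adjust(out$p_deplete, "BH")
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Overlap test between two gene sets
#'
#' Hypergeometric test of the overlap of `set_a` (query) and `set_b`
#' (category) within `universe`; symmetric in its arguments.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector: the gene universe.
#' @param labels length-2 character vector naming the two sets.
#' @return a one-row `enrichment_result` data frame (both tails reported;
#'   `q_*` equals `p_*` for a single test).
#' @export
set_overlap_test <- function(set_a, set_b, universe,
                             labels = c("setA", "setB")) {
  if (!all(set_b %in% universe))
    stop_devodup("setB genes outside the universe")
  hypergeom_enrichment(set_a, setNames(list(set_b), labels[2]), universe,
                       label = labels[1])
}

#' Orthology-class enrichment per bicluster
#'
#' Tests every bicluster's gene set against every orthology class with the
#' exact hypergeometric machinery, Benjamini-Hochberg adjusted over the
#' whole bicluster x class batch, and summarizes how many biclusters are
#' significantly enriched for a chosen class.
#'
#' @param biclusters a `bicluster_set` (or list of lists with `genes`).
#' @param calls an `orthology_result` or its `calls` data frame (columns
#'   gene, class).
#' @param universe gene universe; defaults to all genes with an orthology
#'   call.
#' @param q_threshold significance cut on the BH-adjusted enrichment q
#'   (default 0.05).
#' @param summary_class class counted in the summary line (default
#'   `"conserved_multicopy"`, the lineage-specific duplication signal).
#' @return a list of class `bicluster_enrichment`: `table` (the full
#'   `enrichment_result` batch, q recomputed across the batch),
#'   `n_significant` (biclusters with `q_enrich <= q_threshold` for
#'   `summary_class`), `n_biclusters`, `summary_class` and `q_threshold`.
#' @export
bicluster_class_enrichment <- function(biclusters, calls, universe = NULL,
                                       q_threshold = 0.05,
                                       summary_class = "conserved_multicopy") {
  if (inherits(calls, "orthology_result")) calls <- calls$calls
  stopifnot(all(c("gene", "class") %in% colnames(calls)))
  universe <- universe %||% calls$gene
  classes <- split(calls$gene, calls$class)
  rows <- lapply(seq_along(biclusters), function(i) {
    genes <- biclusters[[i]]$genes
    if (!all(genes %in% universe))
      stop_devodup(sprintf("bicluster %d contains genes outside the universe", i))
    hypergeom_enrichment(genes, classes, universe,
                         label = sprintf("bicluster_%02d", i))
  })
  tab <- do.call(rbind, rows)
  tab$q_enrich <- p.adjust(tab$p_enrich, "BH")
  tab$q_deplete <- p.adjust(tab$p_deplete, "BH")
  sig <- tab[tab$category == summary_class & tab$q_enrich <= q_threshold, ,
             drop = FALSE]
  structure(list(table = tab,
                 n_significant = length(unique(sig$set)),
                 n_biclusters = length(biclusters),
                 summary_class = summary_class,
                 q_threshold = q_threshold),
            class = "bicluster_enrichment")
}

#' @export
print.bicluster_enrichment <- function(x, ...) {
  cat(sprintf("bicluster_enrichment: %d / %d biclusters enriched for %s (q <= %g)\n",
              x$n_significant, x$n_biclusters, x$summary_class, x$q_threshold))
  invisible(x)
}
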