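#' Configuration of the pairwise differential-expression caller
#'
#' The caller is a transparent, pluggable boundary: a pairwise log fold-change
#' rule on pseudocounted expression, optionally gated by a replicate-aware
#' test. Downstream analysis consumes only the resulting ternary calls, so
#' any caller producing \{-1, 0, +1\} per gene and sample pair can substitute
#' (a precomputed ternary matrix can be passed directly to
#' [find_biclusters()]).
#'
#' @param fdr_threshold Benjamini-Hochberg threshold for the optional
#'   replicate-aware gate (default 0.01).
#' @param log2fc_threshold absolute log2 fold-change needed for a call
#'   (default 1).
#' @param pseudocount added to both expression values before the ratio
#'   (default 1).
#' @param expression_floor genes below this value in both samples of a pair
#'   are never called for that pair (default 1).
#' @return a list of class `de_call_config`.
#' @export
de_call_config <- function(fdr_threshold = 0.01, log2fc_threshold = 1.0,
                           pseudocount = 1.0, expression_floor = 1.0) {
  stopifnot(fdr_threshold > 0, log2fc_threshold > 0,
            pseudocount > 0, expression_floor > 0)
  structure(list(fdr_threshold = fdr_threshold,
                 log2fc_threshold = log2fc_threshold,
                 pseudocount = pseudocount,
                 expression_floor = expression_floor),
            class = "de_call_config")
}

#' Ternary pairwise differential-expression matrix
#'
#' For every ordered sample pair (i, j) with i < j in column order, a gene is
#' called +1 if `log2((x_j + c) / (x_i + c)) >= tau`, -1 if `<= -tau`, and 0
#' otherwise (tau = `log2fc_threshold`, c = `pseudocount`); +1 therefore
#' means up in the later-listed sample. Genes below `expression_floor` in
#' both samples of a pair are forced to 0. Ten samples yield the canonical 45
#' comparison columns.
#'
#' When a replicate `groups` factor is supplied, calls are additionally gated
#' by a Welch t-test on `log2(x + c)` between the groups containing samples i
#' and j, Benjamini-Hochberg adjusted across genes within each comparison at
#' `fdr_threshold`; pairs within one group are never called.
#'
#' @param expr numeric genes x samples matrix (>= 2 samples).
#' @param config a [de_call_config()].
#' @param groups optional factor of replicate groups, one per sample.
#' @return an integer genes x pairs matrix of class `ternary_de` with entries
#'   in \{-1, 0, 1\}; columns named `"<i>:<j>"`, pair metadata in attribute
#'   `"pairs"`.
#' @export
call_pairwise_de <- function(expr, config = de_call_config(), groups = NULL) {
  stopifnot(inherits(config, "de_call_config"))
  if (!is.matrix(expr) || !is.numeric(expr)) stop_devodup("'expr' must be a numeric matrix")
  ns <- ncol(expr)
  if (ns < 2) stop_devodup("at least 2 samples are required")
  samples <- colnames(expr) %||% sprintf("s%02d", seq_len(ns))
  pairs <- t(combn(ns, 2))
  cn <- paste(samples[pairs[, 1]], samples[pairs[, 2]], sep = ":")
  cc <- config$pseudocount
  lfc <- log2(expr[, pairs[, 2], drop = FALSE] + cc) -
         log2(expr[, pairs[, 1], drop = FALSE] + cc)
  calls <- matrix(0L, nrow(expr), nrow(pairs))
  calls[lfc >= config$log2fc_threshold] <- 1L
  calls[lfc <= -config$log2fc_threshold] <- -1L
  low <- expr[, pairs[, 1], drop = FALSE] < config$expression_floor &
         expr[, pairs[, 2], drop = FALSE] < config$expression_floor
  calls[low] <- 0L

  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != ns) stop_devodup("'groups' must label every sample")
    lx <- log2(expr + cc)
    gp <- lapply(levels(groups), function(g) which(groups == g))
    names(gp) <- levels(groups)
    pcache <- list()
    for (p in seq_len(nrow(pairs))) {
      gi <- as.character(groups[pairs[p, 1]]); gj <- as.character(groups[pairs[p, 2]])
      if (gi == gj) { calls[, p] <- 0L; next }
      key <- paste(sort(c(gi, gj)), collapse = "|")
      if (is.null(pcache[[key]])) {
        pv <- welch_rowwise(lx[, gp[[gi]], drop = FALSE], lx[, gp[[gj]], drop = FALSE])
        pcache[[key]] <- p.adjust(pv, "BH")
      }
      calls[pcache[[key]] > config$fdr_threshold, p] <- 0L
    }
  }

  dimnames(calls) <- list(rownames(expr), cn)
  attr(calls, "pairs") <- data.frame(i = samples[pairs[, 1]],
                                     j = samples[pairs[, 2]],
                                     stringsAsFactors = FALSE)
  class(calls) <- c("ternary_de", class(calls))
  calls
}

# Row-wise Welch t-test p-values between two sample groups of a log matrix;
# degenerate rows (zero pooled variance or n < 2 on a side) get p = 1.
welch_rowwise <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) return(rep(1, nrow(a)))
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[!is.finite(p)] <- 1
  p
}

#' Housekeeping filter configuration
#'
#' @param floor minimum expression a housekeeping gene must reach in every
#'   sample (default 10, the conventional robust-expression FPKM floor).
#' @return a list of class `housekeeping_config`.
#' @export
housekeeping_config <- function(floor = 10.0) {
  stopifnot(floor > 0)
  structure(list(floor = floor), class = "housekeeping_config")
}

#' Housekeeping genes: robust expression everywhere and never called DE
#'
#' A gene is housekeeping if its expression is at least `floor` in every
#' sample and its ternary row is all zero (no significant differential
#' expression in any pairwise comparison).
#'
#' @param expr numeric genes x samples matrix.
#' @param de a `ternary_de` matrix over the same genes.
#' @param config a [housekeeping_config()].
#' @return character vector of housekeeping gene ids.
#' @export
housekeeping_genes <- function(expr, de, config = housekeeping_config()) {
  stopifnot(inherits(config, "housekeeping_config"))
  if (!identical(rownames(expr), rownames(de)))
    stop_devodup("expression and DE matrices must cover the same genes in the same order")
  robust <- rowSums(expr < config$floor) == 0
  quiet <- rowSums(de != 0L) == 0
  rownames(expr)[robust & quiet]
}

#' Developmentally regulated genes: union of all bicluster members
#'
#' @param biclusters a `bicluster_set` (see [find_biclusters()]) or a plain
#'   list whose elements have a `genes` field.
#' @return character vector of regulated gene ids (sorted, unique).
#' @export
regulated_genes <- function(biclusters) {
  if (length(biclusters) == 0) return(character(0))
  sort(unique(unlist(lapply(biclusters, `[[`, "genes"), use.names = FALSE)))
}

#' Stage-specificity statistic: maximum cross-stage Wilcoxon p-value
#'
#' Pools the per-sample value distributions of each stage group, runs a
#' two-sided Wilcoxon rank-sum test for every pair of stages, and returns the
#' maximum p-value over pairs: the statistic is small only when *every* pair
#' of stages differs. The null is exact (tie-aware full permutation
#' distribution) when both sides have at most `exact_limit` values, and a
#' tie-corrected normal approximation otherwise.
#'
#' @param values either a numeric genes x samples matrix (each column a
#'   distribution of member-gene expression in one sample) or a numeric
#'   vector with one value per sample.
#' @param stages factor assigning each sample (column) to a stage group; all
#'   groups must be nonempty.
#' @param exact_limit exact-null size limit per side (default 12).
#' @return the maximum two-sided p-value over all cross-stage pairs, in
#'   `[0, 1]`.
#' @export
stage_specificity_stat <- function(values, stages, exact_limit = 12L) {
  stages <- as.factor(stages)
  empty <- levels(stages)[tabulate(stages, nbins = nlevels(stages)) == 0]
  if (length(empty))
    stop_devodup("stage group(s) with zero samples: ",
                 paste(empty, collapse = ", "))
  if (is.matrix(values)) {
    if (ncol(values) != length(stages))
      stop_devodup("'stages' must label every sample column")
    pool <- lapply(levels(stages), function(g)
      as.vector(values[, stages == g, drop = FALSE]))
  } else {
    if (length(values) != length(stages))
      stop_devodup("'stages' must label every value")
    pool <- split(as.numeric(values), stages)
  }
  if (any(lengths(pool) == 0)) stop_devodup("every stage group needs at least one sample")
  if (length(pool) < 2) stop_devodup("at least two stage groups are required")
  combos <- combn(length(pool), 2)
  ps <- apply(combos, 2, function(ij)
    wilcox_ranksum_p(pool[[ij[1]]], pool[[ij[2]]], exact_limit))
  max(ps)
}

#' Two-sided Wilcoxon rank-sum p-value (exact and tie-aware for small n)
#'
#' For `length(x)` and `length(y)` both at most `exact_limit` the full
#' permutation null of the rank-sum statistic is computed over midranks by
#' dynamic programming (so ties are handled exactly); the two-sided p-value
#' is `min(1, 2 * min(P(W <= w), P(W >= w)))`. Larger samples use the
#' tie-corrected normal approximation of [stats::wilcox.test()].
#'
#' @param x,y numeric value vectors.
#' @param exact_limit exact-path size limit per side.
#' @return p-value in `[0, 1]`.
#' @export
wilcox_ranksum_p <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (max(pooled) == min(pooled)) return(1)
  if (length(x) <= exact_limit && length(y) <= exact_limit) {
    # scaled midranks are integers (midranks are multiples of 1/2)
    r2 <- as.integer(round(2 * rank(pooled)))
    w <- sum(r2[seq_along(x)])
    dist <- ranksum_null_counts(r2, length(x))
    tot <- sum(dist)
    support <- as.integer(names(dist))
    p_le <- sum(dist[support <= w]) / tot
    p_ge <- sum(dist[support >= w]) / tot
    min(1, 2 * min(p_le, p_ge))
  } else {
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                  correct = TRUE)$p.value)
  }
}

# Counts of subsets of size n1 of the scaled ranks by rank-sum, via the
# generating-function recurrence f_j(s) <- f_j(s) + f_{j-1}(s - r).
ranksum_null_counts <- function(ranks2, n1) {
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1, 1] <- 1
  for (r in ranks2) {
    jmax <- n1
    for (j in jmax:1) {
      src <- f[j, ]
      if (any(src > 0)) {
        idx <- which(src > 0)
        tgt <- idx + r
        keep <- tgt <= smax + 1L
        f[j + 1L, tgt[keep]] <- f[j + 1L, tgt[keep]] + src[idx[keep]]
      }
    }
  }
  counts <- f[n1 + 1L, ]
  names(counts) <- 0:smax
  counts[counts > 0]
}

#' Sample-level overview: correlations, PCA and DE-count clustering
#'
#' Computes (a) the sample x sample Spearman correlation matrix of
#' expression, (b) a PCA of samples with per-component variance fractions
#' (restricted to genes expressed above zero, by default in all samples), and
#' (c) the sample x sample matrix of differential-expression call counts with
#' an average-linkage dendrogram on its Euclidean distances.
#'
#' @param expr numeric genes x samples matrix (>= 3 samples).
#' @param de a `ternary_de` matrix over the same genes.
#' @param pca_gene_filter `"all"` (gene must be > 0 in all samples; default)
#'   or `"any"` (> 0 in at least one sample).
#' @return a list of class `sample_overview`: `spearman` (correlation matrix,
#'   `NA` for constant samples), `constant_samples`, `pca` (variance
#'   fractions and sample scores), `de_counts` (symmetric count matrix),
#'   `dendrogram` (an [stats::hclust] object) and `dendrogram_newick`.
#' @export
sample_overview <- function(expr, de, pca_gene_filter = c("all", "any")) {
  pca_gene_filter <- match.arg(pca_gene_filter)
  if (ncol(expr) < 3) stop_devodup("at least 3 samples are required")
  if (!identical(rownames(expr), rownames(de)))
    stop_devodup("expression and DE matrices must cover the same genes in the same order")
  samples <- colnames(expr)

  constant <- apply(expr, 2, function(v) max(v) == min(v))
  rho <- suppressWarnings(cor(expr, method = "spearman"))
  rho[constant, ] <- NA_real_; rho[, constant] <- NA_real_
  diag(rho) <- 1

  keep <- if (pca_gene_filter == "all") rowSums(expr <= 0) == 0 else rowSums(expr > 0) > 0
  pca <- NULL
  if (sum(keep) >= 2) {
    fit <- prcomp(t(expr[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
    pca <- list(variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
                scores = fit$x, n_genes = sum(keep))
  }

  pairs <- attr(de, "pairs")
  counts <- matrix(0, ncol(expr), ncol(expr), dimnames = list(samples, samples))
  nz <- colSums(de != 0L)
  for (p in seq_len(nrow(pairs))) {
    counts[pairs$i[p], pairs$j[p]] <- nz[p]
    counts[pairs$j[p], pairs$i[p]] <- nz[p]
  }
  hc <- hclust(dist(counts), method = "average")
  structure(list(spearman = rho,
                 constant_samples = samples[constant],
                 pca = pca,
                 de_counts = counts,
                 dendrogram = hc,
                 dendrogram_newick = ape::write.tree(ape::as.phylo(hc))),
            class = "sample_overview")
}

#' @export
print.sample_overview <- function(x, ...) {
  cat(sprintf("sample_overview: %d samples\n", ncol(x$spearman)))
  if (!is.null(x$pca))
    cat(sprintf("  PC1/PC2 variance: %.1f%% / %.1f%% (%d genes)\n",
                100 * x$pca$variance_fraction[1],
                100 * x$pca$variance_fraction[2], x$pca$n_genes))
  cat("  dendrogram:", x$dendrogram_newick, "\n")
  invisible(x)
}
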