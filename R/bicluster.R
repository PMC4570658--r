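#' Biclustering configuration
#'
#' Parameters of the additive sign-consistency score and the greedy search.
#' For a candidate bicluster (gene set G, comparison set C) with per-column
#' signs `s_c`, each cell contributes `+a` if it equals `s_c`, `-b` if it is
#' zero, and `-d` if it carries the opposite sign; the sign of every column
#' is the majority nonzero sign over G (ties resolved to +1), which is the
#' score-optimal choice for any positive weights.
#'
#' @param match_weight,zero_penalty,mismatch_penalty the a, b, d weights
#'   (defaults 1, 1, 2).
#' @param min_genes,min_comparisons minimum bicluster dimensions (defaults 5
#'   and 3).
#' @param score_threshold minimum score of a reported bicluster (default 10).
#' @param max_overlap_jaccard redundancy filter: a bicluster whose gene-set
#'   Jaccard similarity with an already-kept, higher-scoring bicluster
#'   exceeds this value is dropped (default 0.75). Surviving biclusters may
#'   still overlap.
#' @return a list of class `bicluster_config`.
#' @export
bicluster_config <- function(match_weight = 1.0, zero_penalty = 1.0,
                             mismatch_penalty = 2.0,
                             min_genes = 5L, min_comparisons = 3L,
                             score_threshold = 10.0,
                             max_overlap_jaccard = 0.75) {
  stopifnot(match_weight > 0, zero_penalty > 0, mismatch_penalty > 0,
            score_threshold > 0, min_genes >= 1, min_comparisons >= 1,
            max_overlap_jaccard > 0, max_overlap_jaccard <= 1)
  structure(list(match_weight = match_weight, zero_penalty = zero_penalty,
                 mismatch_penalty = mismatch_penalty,
                 min_genes = as.integer(min_genes),
                 min_comparisons = as.integer(min_comparisons),
                 score_threshold = score_threshold,
                 max_overlap_jaccard = max_overlap_jaccard),
            class = "bicluster_config")
}

#' Score a bicluster under the additive sign-consistency model
#'
#' @param matrix ternary genes x comparisons matrix (entries -1/0/+1).
#' @param bicluster a list with `genes`, `comparisons` and `signs` (a +1/-1
#'   vector aligned with `comparisons`).
#' @param config a [bicluster_config()].
#' @return the numeric score.
#' @export
score_bicluster <- function(matrix, bicluster, config = bicluster_config()) {
  stopifnot(inherits(config, "bicluster_config"))
  g <- resolve_idx(bicluster$genes, rownames(matrix), "gene")
  cc <- resolve_idx(bicluster$comparisons, colnames(matrix), "comparison")
  signs <- bicluster$signs
  if (length(signs) != length(cc))
    stop_devodup("sign vector must name every included comparison")
  sub <- matrix[g, cc, drop = FALSE]
  sm <- base::matrix(rep(signs, each = length(g)), nrow = length(g))
  sum(ifelse(sub == sm, config$match_weight,
             ifelse(sub == 0, -config$zero_penalty, -config$mismatch_penalty)))
}

resolve_idx <- function(keys, names, what) {
  if (is.numeric(keys)) {
    idx <- as.integer(keys)
    if (any(idx < 1) || any(idx > length(names)))
      stop_devodup(what, " index out of range")
    return(idx)
  }
  idx <- match(keys, names)
  if (anyNA(idx))
    stop_devodup("unknown ", what, "(s): ",
                 paste(utils::head(keys[is.na(idx)], 5), collapse = ", "))
  idx
}

#' Find sign-consistent biclusters in a ternary DE matrix
#'
#' Deterministic greedy search: (1) every gene pair seeds a candidate with
#' the comparisons on which the two genes carry the same nonzero call (seeds
#' narrower than `min_comparisons` are discarded); (2) from each seed, the
#' single best-scoring addition or removal of one gene or comparison is
#' applied until no move improves the score, with comparison signs always the
#' majority sign over the current genes (ties +1) and all move ties broken by
#' ascending gene/comparison index; (3) local optima meeting the score
#' threshold and size floors are kept; (4) scanning kept biclusters in
#' descending score, any bicluster whose gene-set Jaccard with an
#' already-kept one exceeds `max_overlap_jaccard` is dropped. Reported
#' biclusters may still partially overlap.
#'
#' @param matrix ternary genes x comparisons matrix (entries in -1/0/+1);
#'   dimnames are used for reporting when present.
#' @param config a [bicluster_config()].
#' @return an object of class `bicluster_set`: a list of biclusters, each
#'   with `genes`, `comparisons`, `signs` (named by comparison) and `score`,
#'   ordered by decreasing score.
#' @export
find_biclusters <- function(matrix, config = bicluster_config()) {
  stopifnot(inherits(config, "bicluster_config"))
  if (!is.matrix(matrix) || nrow(matrix) == 0 || ncol(matrix) == 0)
    stop_devodup("'matrix' must be a nonempty matrix")
  vals <- unique(as.vector(matrix))
  if (!all(vals %in% c(-1L, 0L, 1L)))
    stop_devodup("matrix entries must be -1, 0 or +1")
  gn <- rownames(matrix) %||% sprintf("g%d", seq_len(nrow(matrix)))
  cn <- colnames(matrix) %||% sprintf("c%d", seq_len(ncol(matrix)))
  storage.mode(matrix) <- "integer"

  raw <- .bicluster_search_cpp(matrix,
                               config$match_weight, config$zero_penalty,
                               config$mismatch_penalty,
                               config$min_genes, config$min_comparisons,
                               config$score_threshold)
  if (length(raw) == 0)
    return(structure(list(), class = "bicluster_set"))

  # order: decreasing score, ties by lexicographic gene-index key
  scores <- vapply(raw, `[[`, numeric(1), "score")
  keys <- vapply(raw, function(b) paste(b$genes, collapse = ","), character(1))
  raw <- raw[order(-scores, keys)]

  kept <- list()
  kept_genes <- list()
  for (b in raw) {
    gs <- b$genes
    redundant <- any(vapply(kept_genes, function(kg)
      length(intersect(kg, gs)) / length(union(kg, gs)) >
        config$max_overlap_jaccard, logical(1)))
    if (redundant) next
    kept_genes[[length(kept_genes) + 1L]] <- gs
    kept[[length(kept) + 1L]] <- list(
      genes = gn[gs],
      comparisons = cn[b$comparisons],
      signs = setNames(as.integer(b$signs), cn[b$comparisons]),
      score = b$score)
  }
  structure(kept, class = "bicluster_set")
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("bicluster_set: %d bicluster(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  [%d] %d genes x %d comparisons, score %.1f\n",
                i, length(x[[i]]$genes), length(x[[i]]$comparisons),
                x[[i]]$score))
  invisible(x)
}

#' Per-sample expression profile of a bicluster's member genes
#'
#' Summarizes the distribution of member-gene expression in every sample
#' (median and quartiles) and attaches the cross-stage specificity statistic
#' ([stage_specificity_stat()]): the maximum pairwise Wilcoxon p-value over
#' stage groups.
#'
#' @param bicluster an element of a `bicluster_set` (or any list with a
#'   `genes` field).
#' @param expr numeric genes x samples matrix.
#' @param stages factor assigning samples to stage groups; defaults to the
#'   `"stages"` attribute of `expr` when present.
#' @return a list of class `bicluster_profile`: `summary` (data frame with
#'   sample, q25, median, q75), `n_genes`, and `stage_specificity_p`.
#' @export
bicluster_stage_profile <- function(bicluster, expr,
                                    stages = attr(expr, "stages")) {
  genes <- intersect(bicluster$genes, rownames(expr))
  if (length(genes) == 0)
    stop_devodup("no bicluster member genes present in the expression table")
  sub <- expr[genes, , drop = FALSE]
  qs <- apply(sub, 2, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  out <- data.frame(sample = colnames(expr),
                    q25 = qs[1, ], median = qs[2, ], q75 = qs[3, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  p <- if (!is.null(stages)) stage_specificity_stat(sub, stages) else NA_real_
  structure(list(summary = out, n_genes = length(genes),
                 stage_specificity_p = p),
            class = "bicluster_profile")
}
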