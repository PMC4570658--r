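#' Orthology-procedure configuration
#'
#' @param focal_species species tag of the proteome being classified.
#' @param comparison_species species used for one-to-one ortholog calls
#'   (must be part of the panel).
#' @param panel_species all non-focal species whose hits count towards
#'   homolog (conserved vs orphan) status; defaults to just the comparison
#'   species.
#' @param evalue_threshold hits with e-value strictly below this value are
#'   considered (default 0.001).
#' @return a list of class `orthology_config`.
#' @export
orthology_config <- function(focal_species, comparison_species,
                             panel_species = comparison_species,
                             evalue_threshold = 0.001) {
  stopifnot(evalue_threshold > 0)
  if (focal_species %in% panel_species)
    stop_devodup("the focal species cannot be part of the comparison panel")
  if (!comparison_species %in% panel_species)
    stop_devodup("the comparison species must be part of the panel")
  structure(list(focal_species = focal_species,
                 comparison_species = comparison_species,
                 panel_species = panel_species,
                 evalue_threshold = evalue_threshold),
            class = "orthology_config")
}

filter_hits <- function(hits, config) {
  hits[hits$evalue < config$evalue_threshold, , drop = FALSE]
}

#' Best cross-species hit per gene
#'
#' For focal-species genes, the best (highest bit score) hit to the
#' comparison species; for comparison-species genes, the best hit to the
#' focal species. Ties are broken by smaller e-value, then lexicographically
#' by subject id. Genes without a qualifying hit get a score of 0 and no
#' subject.
#'
#' @param hits a `similarity_hits` data frame.
#' @param config an [orthology_config()].
#' @return a data frame (gene, species, best_bitscore, best_subject,
#'   best_evalue) covering every focal/comparison-species gene seen as a
#'   query or subject.
#' @export
best_interspecies_scores <- function(hits, config) {
  stopifnot(inherits(config, "orthology_config"))
  h <- filter_hits(hits, config)
  fs <- config$focal_species; cs <- config$comparison_species
  all_genes <- unique(rbind(
    data.frame(gene = hits$query, species = hits$query_species),
    data.frame(gene = hits$subject, species = hits$subject_species)))
  all_genes <- all_genes[all_genes$species %in% c(fs, cs), , drop = FALSE]

  cross <- h[(h$query_species == fs & h$subject_species == cs) |
             (h$query_species == cs & h$subject_species == fs), , drop = FALSE]
  o <- order(cross$query, -cross$bitscore, cross$evalue, cross$subject)
  cross <- cross[o, , drop = FALSE]
  top <- cross[!duplicated(cross$query), , drop = FALSE]

  idx <- match(all_genes$gene, top$query)
  out <- data.frame(
    gene = all_genes$gene,
    species = all_genes$species,
    best_bitscore = ifelse(is.na(idx), 0, top$bitscore[idx]),
    best_subject = ifelse(is.na(idx), NA_character_, top$subject[idx]),
    best_evalue = ifelse(is.na(idx), NA_real_, top$evalue[idx]),
    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  out
}

#' Inparalog detection
#'
#' A gene `a` has an inparalog if some same-species hit (a, a') scores
#' strictly higher than `a`'s best cross-species hit, i.e. the duplication
#' post-dates the speciation under a molecular clock. The rule is evaluated
#' directionally by default; the symmetric variant flags the pair only when
#' the intraspecies score beats the best cross-species score of *both*
#' genes. Genes with no cross-species hit (best score 0) are never flagged;
#' they cannot enter a reciprocal-best pair anyway.
#'
#' @param hits a `similarity_hits` data frame. With
#'   `intraspecies_only = TRUE` the table must contain only same-species
#'   rows and any cross-species row is an error; by default cross-species
#'   rows are ignored.
#' @param best output of [best_interspecies_scores()].
#' @param config an [orthology_config()].
#' @param symmetric logical; use the two-directional variant.
#' @param intraspecies_only logical; reject cross-species rows instead of
#'   ignoring them.
#' @return a list with `flags` (named logical over the genes of `best`) and
#'   `pairs` (data frame gene, inparalog, bitscore).
#' @export
find_inparalogs <- function(hits, best, config, symmetric = FALSE,
                            intraspecies_only = FALSE) {
  stopifnot(inherits(config, "orthology_config"))
  if (intraspecies_only && any(hits$query_species != hits$subject_species))
    stop_devodup("cross-species hit routed into inparalog detection")
  h <- filter_hits(hits, config)
  h <- h[h$query_species == h$subject_species &
         h$query_species %in% c(config$focal_species, config$comparison_species), ,
         drop = FALSE]
  bstar <- setNames(best$best_bitscore, best$gene)
  bq <- bstar[h$query]
  flag <- !is.na(bq) & bq > 0 & h$bitscore > bq
  if (symmetric) {
    bs <- bstar[h$subject]
    flag <- flag & !is.na(bs) & bs > 0 & h$bitscore > bs
  }
  pairs <- data.frame(gene = h$query[flag], inparalog = h$subject[flag],
                      bitscore = h$bitscore[flag], stringsAsFactors = FALSE)
  flags <- setNames(best$gene %in% pairs$gene, best$gene)
  list(flags = flags, pairs = pairs)
}

#' One-to-one orthologs by inparalog-vetoed reciprocal best hits
#'
#' Reports a pair (a, b) iff `b` is `a`'s best comparison-species hit, `a`
#' is `b`'s best focal-species hit, and neither gene has an inparalog. Each
#' gene appears in at most one pair.
#'
#' @param best output of [best_interspecies_scores()].
#' @param inparalogs output of [find_inparalogs()].
#' @param config an [orthology_config()].
#' @return a data frame (focal, comparison, bitscore), sorted by focal id.
#' @export
one_to_one_orthologs <- function(best, inparalogs, config) {
  stopifnot(inherits(config, "orthology_config"))
  flags <- inparalogs$flags
  fo <- best[best$species == config$focal_species & best$best_bitscore > 0, ,
             drop = FALSE]
  if (nrow(fo) == 0)
    return(data.frame(focal = character(0), comparison = character(0),
                      bitscore = numeric(0)))
  partner_best <- best[match(fo$best_subject, best$gene), "best_subject"]
  reciprocal <- !is.na(partner_best) & partner_best == fo$gene
  vetoed <- flags[fo$gene] | flags[fo$best_subject]
  vetoed[is.na(vetoed)] <- FALSE
  keep <- reciprocal & !vetoed
  out <- data.frame(focal = fo$gene[keep], comparison = fo$best_subject[keep],
                    bitscore = fo$best_bitscore[keep], stringsAsFactors = FALSE)
  out <- out[order(out$focal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paralog families as connected components of the intraspecies hit graph
#'
#' Builds the undirected graph over focal-species genes with an edge
#' wherever a same-species hit in either direction passes the e-value
#' threshold, and labels connected components. Genes in `genes` that carry
#' no hit become singleton components.
#'
#' @param hits a `similarity_hits` data frame.
#' @param config an [orthology_config()].
#' @param genes optional character vector: the full focal gene universe.
#' @return a data frame (gene, component, component_size).
#' @export
paralog_components <- function(hits, config, genes = NULL) {
  stopifnot(inherits(config, "orthology_config"))
  h <- filter_hits(hits, config)
  h <- h[h$query_species == config$focal_species &
         h$subject_species == config$focal_species, , drop = FALSE]
  seen <- unique(c(h$query, h$subject,
                   hits$query[hits$query_species == config$focal_species],
                   hits$subject[hits$subject_species == config$focal_species]))
  verts <- sort(unique(c(seen, genes)))
  if (length(verts) == 0)
    return(data.frame(gene = character(0), component = integer(0),
                      component_size = integer(0)))
  g <- igraph::graph_from_data_frame(
    h[c("query", "subject")], directed = FALSE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  out <- data.frame(gene = verts,
                    component = as.integer(comp$membership[verts]),
                    component_size = as.integer(comp$csize[comp$membership[verts]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  out
}

#' Five-class orthology partition of the focal proteome
#'
#' Runs the full procedure — best cross-species hits, inparalog detection,
#' inparalog-vetoed reciprocal best hits, panel homolog status, paralog
#' components — and assigns every focal gene to exactly one class, by
#' priority:
#'
#' 1. `one_to_one`: member of a reported reciprocal-best pair;
#' 2. otherwise `conserved` vs `orphan`, by presence of any panel-species
#'    hit below the e-value threshold (genes absent from all hit tables are
#'    orphans);
#' 3. within each, `multicopy` vs `singleton` by paralog-component size
#'    among the *non*-one-to-one genes: one-to-one genes are removed before
#'    the subdivision, so a one-to-one gene never counts as multicopy and a
#'    gene whose only paralog partners are one-to-one genes is a singleton.
#'
#' @param hits a `similarity_hits` data frame covering focal-vs-panel and
#'   focal-vs-focal (and comparison-vs-comparison, for the inparalog veto)
#'   hits.
#' @param config an [orthology_config()].
#' @param genes optional full focal gene universe (ids absent from the hit
#'   tables are classified as orphan singletons).
#' @param symmetric_inparalogs logical, passed to [find_inparalogs()].
#' @return an object of class `orthology_result`: list with `calls` (data
#'   frame gene, class, component, component_size, partner, has_inparalog,
#'   best_interspecies_bitscore), `pairs`, `components`, `best` and
#'   `config`.
#' @export
classify_genes <- function(hits, config, genes = NULL,
                           symmetric_inparalogs = FALSE) {
  stopifnot(inherits(config, "orthology_config"))
  best <- best_interspecies_scores(hits, config)
  inpar <- find_inparalogs(hits, best, config, symmetric = symmetric_inparalogs)
  pairs <- one_to_one_orthologs(best, inpar, config)

  h <- filter_hits(hits, config)
  panel_hit <- unique(c(
    h$query[h$query_species == config$focal_species &
            h$subject_species %in% config$panel_species],
    h$subject[h$subject_species == config$focal_species &
              h$query_species %in% config$panel_species]))

  focal_seen <- unique(c(
    hits$query[hits$query_species == config$focal_species],
    hits$subject[hits$subject_species == config$focal_species]))
  universe <- sort(unique(c(focal_seen, genes)))
  if (length(universe) == 0) stop_devodup("no focal-species genes to classify")

  # components among non-one-to-one genes only: remove 1:1 genes, then relabel
  non_oto <- setdiff(universe, pairs$focal)
  sub_hits <- hits[!(hits$query %in% pairs$focal) &
                   !(hits$subject %in% pairs$focal), , drop = FALSE]
  comps <- paralog_components(sub_hits, config, genes = non_oto)

  cls <- setNames(rep(NA_character_, length(universe)), universe)
  cls[pairs$focal] <- "one_to_one"
  conserved <- universe %in% panel_hit
  size <- setNames(rep(1L, length(universe)), universe)
  size[comps$gene] <- comps$component_size
  multi <- size > 1L
  open <- is.na(cls)
  cls[open & conserved & multi] <- "conserved_multicopy"
  cls[open & conserved & !multi] <- "conserved_singleton"
  cls[open & !conserved & multi] <- "orphan_multicopy"
  cls[open & !conserved & !multi] <- "orphan_singleton"

  comp_id <- setNames(rep(NA_integer_, length(universe)), universe)
  comp_id[comps$gene] <- comps$component
  bt <- best[match(universe, best$gene), ]
  calls <- data.frame(
    gene = universe,
    class = unname(cls),
    component = unname(comp_id),
    component_size = unname(size),
    partner = pairs$comparison[match(universe, pairs$focal)],
    has_inparalog = unname(inpar$flags[universe] %in% TRUE),
    best_interspecies_bitscore = ifelse(is.na(bt$best_bitscore), 0,
                                        bt$best_bitscore),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(calls = calls, pairs = pairs, components = comps,
                 best = best, inparalogs = inpar, config = config),
            class = "orthology_result")
}

#' @export
print.orthology_result <- function(x, ...) {
  n <- nrow(x$calls)
  cat(sprintf("orthology_result: %d focal genes, %d one-to-one pairs\n",
              n, nrow(x$pairs)))
  tab <- table(x$calls$class)
  for (cl in names(tab))
    cat(sprintf("  %-20s %6d (%.1f%%)\n", cl, tab[[cl]], 100 * tab[[cl]] / n))
  invisible(x)
}

#' Compare one-to-one predictions with a manually curated set
#'
#' The curated table lists comparison-species genes with a manual verdict on
#' whether a one-to-one ortholog exists in the focal species. A curated gene
#' is "predicted" when it appears as the comparison member of a reported
#' reciprocal-best pair. Curated genes absent from the hit universe are
#' counted separately as unassessable.
#'
#' @param result an `orthology_result` from [classify_genes()].
#' @param curated data frame with columns `gene` and `has_one_to_one`
#'   (logical manual verdict).
#' @return a list of class `curated_evaluation` with the confusion counts
#'   (`tp`, `fn`, `tn`, `fp`), `unassessable`, and agreement fractions
#'   `sensitivity` (manual positives predicted) and `specificity` (manual
#'   negatives not predicted).
#' @export
evaluate_against_curated <- function(result, curated) {
  stopifnot(inherits(result, "orthology_result"),
            all(c("gene", "has_one_to_one") %in% colnames(curated)))
  cfg <- result$config
  universe <- result$best$gene[result$best$species == cfg$comparison_species]
  assessable <- curated$gene %in% universe
  predicted <- curated$gene %in% result$pairs$comparison
  pos <- curated$has_one_to_one & assessable
  neg <- !curated$has_one_to_one & assessable
  structure(list(
    tp = sum(pos & predicted), fn = sum(pos & !predicted),
    tn = sum(neg & !predicted), fp = sum(neg & predicted),
    unassessable = sum(!assessable),
    sensitivity = if (sum(pos)) sum(pos & predicted) / sum(pos) else NA_real_,
    specificity = if (sum(neg)) sum(neg & !predicted) / sum(neg) else NA_real_),
    class = "curated_evaluation")
}

#' @export
print.curated_evaluation <- function(x, ...) {
  cat(sprintf("curated_evaluation: TP %d, FN %d, TN %d, FP %d (%d unassessable)\n",
              x$tp, x$fn, x$tn, x$fp, x$unassessable))
  cat(sprintf("  sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}
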