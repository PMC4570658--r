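#' Within-family expression-profile correlation of paralogs
#'
#' For every paralog family with at least two expressed members, computes
#' all within-family pairwise Spearman correlations of expression profiles
#' and summarizes each family by the median correlation. A background
#' distribution of correlations between randomly paired genes from
#' *different* families (resampled with a fixed seed) yields an empirical
#' upper-tail p-value per family: the fraction of background pairs at least
#' as correlated as the family median.
#'
#' @param expr numeric genes x samples matrix.
#' @param families named character/integer vector mapping gene -> family id
#'   (e.g. the `component` column of [paralog_components()]), or that data
#'   frame itself.
#' @param n_background number of background cross-family pairs (default
#'   1000).
#' @param seed integer seed for the background resampling.
#' @return a list of class `paralog_correlation`: `families` (data frame
#'   family, n_members, n_pairs, median_rho, p_empirical), `background_rho`
#'   (numeric vector) and `skipped` (families with fewer than two expressed
#'   members).
#' @export
paralog_profile_correlation <- function(expr, families, n_background = 1000L,
                                        seed = 1L) {
  if (is.data.frame(families)) {
    stopifnot(all(c("gene", "component") %in% colnames(families)))
    families <- setNames(families$component, families$gene)
  }
  if (is.null(names(families))) stop_devodup("'families' must be named by gene id")
  fam <- families[names(families) %in% rownames(expr)]
  groups <- split(names(fam), as.character(fam))
  sizes <- lengths(groups)
  skipped <- names(groups)[sizes < 2]
  groups <- groups[sizes >= 2]
  if (length(groups) == 0)
    stop_devodup("no family has two or more expressed members")

  per_family <- lapply(names(groups), function(f) {
    sub <- expr[groups[[f]], , drop = FALSE]
    rho <- suppressWarnings(cor(t(sub), method = "spearman"))
    vals <- rho[upper.tri(rho)]
    data.frame(family = f, n_members = nrow(sub),
               n_pairs = length(vals),
               median_rho = median(vals, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  fam_df <- do.call(rbind, per_family)

  expressed <- intersect(names(fam), rownames(expr))
  bg <- with_local_seed(seed, {
    out <- numeric(0)
    guard <- 0L
    while (length(out) < n_background && guard < 50L) {
      i <- sample(expressed, n_background, replace = TRUE)
      j <- sample(expressed, n_background, replace = TRUE)
      ok <- as.character(fam[i]) != as.character(fam[j])
      ii <- i[ok]; jj <- j[ok]
      if (length(ii)) {
        rho <- vapply(seq_along(ii), function(p)
          suppressWarnings(cor(expr[ii[p], ], expr[jj[p], ],
                               method = "spearman")), numeric(1))
        out <- c(out, rho)
      }
      guard <- guard + 1L
    }
    utils::head(out, n_background)
  })
  if (length(bg) == 0) stop_devodup("could not draw cross-family background pairs")
  fam_df$p_empirical <- vapply(fam_df$median_rho, function(m)
    (1 + sum(bg >= m, na.rm = TRUE)) / (1 + sum(!is.na(bg))), numeric(1))
  structure(list(families = fam_df, background_rho = bg, skipped = skipped),
            class = "paralog_correlation")
}

#' @export
print.paralog_correlation <- function(x, ...) {
  cat(sprintf(
    "paralog_correlation: %d families (median within-family rho %.3f; background median %.3f)\n",
    nrow(x$families), median(x$families$median_rho),
    median(x$background_rho, na.rm = TRUE)))
  invisible(x)
}

#' Maximal focal-species-specific clades of a gene tree
#'
#' Finds every maximal clade whose tips all belong to the focal species and
#' that contains at least two tips: the subtrees produced by duplications on
#' the focal lineage. Maximality means the parent clade contains a
#' non-focal tip (the clade spanning the whole tree is reported when every
#' tip is focal). Unrooted input is first rooted at the midpoint of the
#' path between the two most distant non-focal tips (falling back to an
#' outgroup rooting on the single non-focal tip, or to the stored
#' orientation when no non-focal tip exists).
#'
#' @param gene_tree a `gene_tree` from [read_newick()] (or a list with
#'   `tree` and `species`).
#' @param focal_species species tag of the focal lineage.
#' @param regulated,one_to_one optional character vectors used to annotate
#'   each clade with its count of regulated and one-to-one member genes.
#' @return a list of class `clade_report`: `clades` (list of tip-label
#'   vectors) and `summary` (data frame clade, size, n_regulated,
#'   n_one_to_one, all of whose clades are all-focal by construction).
#' @export
lineage_specific_clades <- function(gene_tree, focal_species,
                                    regulated = character(0),
                                    one_to_one = character(0)) {
  tree <- gene_tree$tree
  species <- gene_tree$species
  focal <- names(species)[species == focal_species]
  empty <- structure(list(clades = list(),
                          summary = data.frame(clade = integer(0),
                                               size = integer(0),
                                               n_regulated = integer(0),
                                               n_one_to_one = integer(0))),
                     class = "clade_report")
  if (length(focal) == 0) return(empty)
  if (length(tree$tip.label) == 1) {
    return(empty)  # a single-tip tree has no clade of size >= 2
  }
  if (!ape::is.rooted(tree)) tree <- root_by_nonfocal(tree, species, focal_species)

  ntip <- length(tree$tip.label)
  is_focal_tip <- tree$tip.label %in% focal
  # postorder sweep: does every tip below each node belong to the focal species?
  nnode <- ntip + tree$Nnode
  allfocal <- c(is_focal_tip, rep(TRUE, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    allfocal[par] <- allfocal[par] && allfocal[child]
  }
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L

  internal <- (ntip + 1L):nnode
  maximal <- internal[allfocal[internal] &
                      (is.na(parent[internal]) | !allfocal[parent[internal]])]
  tipsets <- lapply(maximal, function(nd)
    ape::extract.clade(tree, nd)$tip.label)
  tipsets <- tipsets[lengths(tipsets) >= 2]
  if (length(tipsets) == 0) return(empty)
  summary <- data.frame(
    clade = seq_along(tipsets),
    size = lengths(tipsets),
    n_regulated = vapply(tipsets, function(t) sum(t %in% regulated), integer(1)),
    n_one_to_one = vapply(tipsets, function(t) sum(t %in% one_to_one), integer(1)))
  structure(list(clades = tipsets, summary = summary), class = "clade_report")
}

# Root an unrooted tree at the midpoint of the path between the two most
# distant non-focal tips (ties broken lexicographically); with one non-focal
# tip, use it as outgroup; with none, keep the stored orientation.
root_by_nonfocal <- function(tree, species, focal_species) {
  nonfocal <- tree$tip.label[species[tree$tip.label] != focal_species]
  if (length(nonfocal) == 0)
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  if (length(nonfocal) == 1)
    return(ape::root(tree, outgroup = nonfocal, resolve.root = TRUE))
  if (is.null(tree$edge.length))
    return(ape::root(tree, outgroup = nonfocal[order(nonfocal)][1],
                     resolve.root = TRUE))
  dd <- ape::cophenetic.phylo(tree)[nonfocal, nonfocal, drop = FALSE]
  idx <- which(dd == max(dd), arr.ind = TRUE)
  pick <- idx[order(rownames(dd)[idx[, 1]], colnames(dd)[idx[, 2]]), , drop = FALSE][1, ]
  a <- rownames(dd)[pick[1]]; b <- colnames(dd)[pick[2]]
  target <- dd[a, b] / 2
  path <- ape::nodepath(tree, which(tree$tip.label == a),
                        which(tree$tip.label == b))
  acc <- 0
  for (i in seq_len(length(path) - 1L)) {
    eidx <- which((tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1]) |
                  (tree$edge[, 1] == path[i + 1] & tree$edge[, 2] == path[i]))
    len <- tree$edge.length[eidx]
    if (acc + len >= target) {
      # distance from the child endpoint of this edge to the new root
      child <- tree$edge[eidx, 2]
      child_is_near <- child == path[i]
      pos <- if (child_is_near) target - acc else len - (target - acc)
      rooted <- phytools::reroot(tree, child, position = pos)
      return(rooted)
    }
    acc <- acc + len
  }
  ape::root(tree, outgroup = a, resolve.root = TRUE)  # numeric fallback
}

#' Association between lineage-specific clades and developmental regulation
#'
#' Formalizes the qualitative observation that regulated genes cluster in
#' focal-species-specific subtrees: a 2x2 hypergeometric association between
#' membership in any reported lineage-specific clade and membership in the
#' regulated set, over the universe of tree tips. Additionally counts the
#' regulated genes among the tips that have one-to-one orthologs.
#'
#' @param clade_report a `clade_report` from [lineage_specific_clades()].
#' @param regulated character vector of regulated gene ids.
#' @param universe character vector of tree tips to consider (the focal-tip
#'   universe).
#' @param one_to_one optional character vector of genes with one-to-one
#'   orthologs.
#' @return a list of class `clade_association`: `defined` (FALSE when there
#'   is no lineage-specific clade, in which case the test is flagged as
#'   undefined), `test` (a one-row `enrichment_result` or NULL),
#'   `n_regulated_one_to_one`, and the in-clade/regulated counts.
#' @export
clade_regulation_association <- function(clade_report, regulated, universe,
                                         one_to_one = character(0)) {
  if (length(universe) == 0) stop_devodup("empty universe")
  universe <- unique(universe)
  in_clade <- intersect(unique(unlist(clade_report$clades)), universe)
  reg <- intersect(regulated, universe)
  n_roto <- length(intersect(intersect(reg, one_to_one), universe))
  if (length(in_clade) == 0) {
    return(structure(list(defined = FALSE, test = NULL,
                          n_in_clade = 0L, n_regulated = length(reg),
                          n_regulated_one_to_one = n_roto),
                     class = "clade_association"))
  }
  test <- set_overlap_test(in_clade, reg, universe,
                           labels = c("lineage_specific_clades", "regulated"))
  structure(list(defined = TRUE, test = test,
                 n_in_clade = length(in_clade), n_regulated = length(reg),
                 n_regulated_one_to_one = n_roto),
            class = "clade_association")
}

#' @export
print.clade_association <- function(x, ...) {
  if (!x$defined) {
    cat("clade_association: undefined (no lineage-specific clades)\n")
  } else {
    cat(sprintf(
      "clade_association: %d in-clade tips, %d regulated, overlap %d, enrichment p = %.3g\n",
      x$n_in_clade, x$n_regulated, x$test$k, x$test$p_enrich))
  }
  cat(sprintf("  regulated genes with one-to-one orthologs: %d\n",
              x$n_regulated_one_to_one))
  invisible(x)
}
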