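#' Read an all-vs-all similarity table in BLAST tabular (outfmt 6) layout
#'
#' Expects 12 tab-separated columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore); only query,
#' subject, e-value and bit score are used. Self-hits are dropped, duplicate
#' (query, subject) pairs are collapsed keeping the best (highest) bit score
#' with ties resolved by the smaller e-value, and every gene must resolve to a
#' species through `species`.
#'
#' @param path path to the tab-separated hit table (no header).
#' @param species species assignment: either a named character vector mapping
#'   gene id -> species tag, or a named character vector of regular
#'   expressions (`patterns = TRUE`) where the first matching pattern names
#'   the species.
#' @param patterns logical; interpret `species` as regex patterns applied to
#'   gene ids rather than as a direct gene -> species lookup.
#' @return a `similarity_hits` data frame with columns query, subject,
#'   evalue, bitscore, query_species, subject_species.
#' @export
read_similarity_table <- function(path, species, patterns = FALSE) {
  if (!file.exists(path)) stop_devodup("no such file: ", path)
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
  if (ncol(raw) < 12)
    stop_devodup("expected 12 tab-separated columns (BLAST outfmt 6), found ", ncol(raw))
  evalue <- suppressWarnings(as.numeric(raw[[11]]))
  bitscore <- suppressWarnings(as.numeric(raw[[12]]))
  bad <- which(is.na(evalue) | is.na(bitscore) | evalue < 0 | bitscore < 0)
  if (length(bad))
    stop_devodup("unparseable or negative evalue/bitscore at line(s): ",
                 paste(utils::head(bad, 10), collapse = ", "))
  hits <- data.frame(query = raw[[1]], subject = raw[[2]],
                     evalue = evalue, bitscore = bitscore,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]

  ids <- unique(c(hits$query, hits$subject))
  sp <- assign_species(ids, species, patterns)
  hits$query_species <- unname(sp[hits$query])
  hits$subject_species <- unname(sp[hits$subject])

  # collapse duplicates: best bitscore, then smallest e-value
  o <- order(hits$query, hits$subject, -hits$bitscore, hits$evalue)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("query", "subject")]), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("similarity_hits", "data.frame")
  hits
}

assign_species <- function(ids, species, patterns) {
  if (is.null(names(species)) || !is.character(species))
    stop_devodup("'species' must be a named character vector")
  if (patterns) {
    sp <- rep(NA_character_, length(ids))
    for (tag in names(species)) {
      hit <- is.na(sp) & grepl(species[[tag]], ids)
      sp[hit] <- tag
    }
    names(sp) <- ids
  } else {
    sp <- species[ids]
    names(sp) <- ids
  }
  missing <- ids[is.na(sp)]
  if (length(missing))
    stop_devodup("no species assignment for gene(s): ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  sp
}

#' Write similarity hits as 12-column BLAST tabular rows
#'
#' Unused alignment columns (pident, length, mismatch, gapopen, coordinates)
#' are filled with placeholder values; e-values and bit scores are written at
#' 6 significant digits, the declared round-trip precision.
#'
#' @param hits a `similarity_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  out <- data.frame(hits$query, hits$subject, 100, 0, 0, 0, 0, 0, 0, 0,
                    signif(hits$evalue, 6), signif(hits$bitscore, 6))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression table
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' Values must parse as non-negative numbers; duplicate gene ids, duplicate
#' sample ids, negative values and missing cells are hard errors.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix (genes x samples).
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_devodup("no such file: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop_devodup("expected gene id column plus >=1 sample column")
  genes <- raw[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop_devodup("duplicated gene id(s): ", paste(utils::head(dup, 10), collapse = ", "))
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) stop_devodup("duplicated sample ids in header")
  vals <- vapply(raw[-1], function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw), dimnames = list(genes, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_devodup(sprintf("missing or non-numeric value for gene '%s', sample '%s'",
                         genes[bad[1]], samples[bad[2]]))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop_devodup(sprintf("negative expression value for gene '%s', sample '%s'",
                         genes[bad[1]], samples[bad[2]]))
  }
  vals
}

#' Write a gene x sample expression table as TSV
#'
#' @param expr numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr), signif(expr, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene tree in Newick format with species-resolved tips
#'
#' Parses the tree with \pkg{ape} and assigns every tip to a species via
#' regular-expression rules (e.g. `c(Ppa = "^Ppa-", Cel = "^Cel-")`); the
#' first matching rule wins and a tip matching no rule is an error.
#'
#' @param path path to a Newick file (or a Newick string containing ";").
#' @param species_rules named character vector of regex patterns; names are
#'   species tags.
#' @return an object of class `gene_tree`: a list with `tree` (an
#'   \pkg{ape} `phylo`) and `species` (named character vector over tips).
#' @export
read_newick <- function(path, species_rules) {
  tree <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop_devodup("could not parse Newick input")
  sp <- assign_species(tree$tip.label, species_rules, patterns = TRUE)
  structure(list(tree = tree, species = sp), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree: %d tips (%s)\n", length(x$tree$tip.label),
              paste(sprintf("%s: %d", names(table(x$species)),
                            table(x$species)), collapse = ", ")))
  invisible(x)
}

#' Write / read a simulation truth table as TSV
#'
#' The gene-level table of a `family_truth` object round-trips through a
#' plain TSV (gene, species, family, class, regulated, archetype).
#'
#' @param truth a `family_truth` object (for writing).
#' @param path file path.
#' @return `write_truth_table` returns `path` invisibly; `read_truth_table`
#'   returns the gene-level data frame.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "family_truth"))
  cols <- c("gene", "species", "family", "class", "regulated", "archetype")
  write.table(truth$genes[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stop_devodup("no such file: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("gene", "species", "family", "class", "regulated")
  miss <- setdiff(needed, colnames(df))
  if (length(miss)) stop_devodup("truth table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene)) stop_devodup("truth table has duplicated gene ids")
  df$regulated <- as.logical(df$regulated)
  df
}

#' Read a gene annotation table (gene <TAB> category)
#'
#' Two-column TSV mapping genes to annotation categories such as protein
#' domains; a gene may carry several categories (one row each).
#'
#' @param path file path.
#' @param header logical; whether the file has a header row.
#' @return a named list: category -> character vector of gene ids.
#' @export
read_annotation_table <- function(path, header = FALSE) {
  if (!file.exists(path)) stop_devodup("no such file: ", path)
  df <- read.delim(path, header = header, sep = "\t",
                   colClasses = "character", quote = "")
  if (ncol(df) < 2) stop_devodup("expected two tab-separated columns (gene, category)")
  split(df[[1]], df[[2]])
}
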