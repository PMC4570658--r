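# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# brute force over all gene subsets (>= min_genes) and comparison subsets,
# with the per-column score maximized over the two signs
oracle_bicluster_max <- function(m, a = 1, b = 1, d = 2, min_genes = 2) {
  n <- nrow(m)
  if (n < min_genes) return(-Inf)
  best <- -Inf
  gene_sets <- unlist(lapply(min_genes:n, function(k)
    combn(n, k, simplify = FALSE)), recursive = FALSE)
  for (g in gene_sets) {
    sub <- m[g, , drop = FALSE]
    np <- colSums(sub == 1); nm <- colSums(sub == -1); n0 <- colSums(sub == 0)
    csc <- a * pmax(np, nm) - d * pmin(np, nm) - b * n0
    s <- if (any(csc > 0)) sum(csc[csc > 0]) else max(csc)
    best <- max(best, s)
  }
  best
}

# two-sided rank-sum p by explicit enumeration of all group assignments
oracle_wilcox_two_sided <- function(x, y) {
  pooled <- c(x, y)
  if (max(pooled) == min(pooled)) return(1)
  r <- rank(pooled)
  n1 <- length(x); N <- length(pooled)
  w_obs <- sum(r[seq_len(n1)])
  ws <- combn(N, n1, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# hypergeometric tails by direct binomial-coefficient summation
oracle_hyper_upper <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
oracle_hyper_lower <- function(k, K, n, N) {
  kk <- max(0, n + K - N):k
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# connected-component labelling by repeated adjacency-matrix squaring
oracle_components <- function(edges, genes) {
  n <- length(genes)
  A <- diag(1, n)
  rownames(A) <- colnames(A) <- genes
  for (e in seq_len(nrow(edges))) {
    A[edges[e, 1], edges[e, 2]] <- 1
    A[edges[e, 2], edges[e, 1]] <- 1
  }
  repeat {
    A2 <- (A %*% A > 0) * 1
    if (identical(A2, A)) break
    A <- A2
  }
  labels <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      next_id <- next_id + 1L
      labels[A[i, ] > 0] <- next_id
    }
  }
  setNames(labels, genes)
}

# similarity-hit table builder for hand-crafted orthology cases;
# species derived from the id prefix before the first underscore
make_hits <- function(...) {
  h <- data.frame(..., stringsAsFactors = FALSE)
  stopifnot(all(c("query", "subject", "bitscore") %in% colnames(h)))
  if (is.null(h$evalue)) h$evalue <- 10^(-h$bitscore / 10)
  sp <- function(id) sub("_.*$", "", id)
  h$query_species <- sp(h$query)
  h$subject_species <- sp(h$subject)
  class(h) <- c("similarity_hits", "data.frame")
  h
}

# both directed rows for a symmetric hit
sym_hits <- function(...) {
  h <- make_hits(...)
  rev <- h
  rev$query <- h$subject; rev$subject <- h$query
  rev$query_species <- h$subject_species; rev$subject_species <- h$query_species
  out <- rbind(h, rev)
  class(out) <- c("similarity_hits", "data.frame")
  out
}
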