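make_expr <- function(vals, samples = NULL) {
  m <- do.call(rbind, vals)
  rownames(m) <- names(vals)
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ten samples yield the canonical 45 comparison columns", {
  expr <- matrix(runif(50, 1, 100), 5, 10,
                 dimnames = list(paste0("g", 1:5), sprintf("s%02d", 1:10)))
  de <- call_pairwise_de(expr)
  expect_equal(ncol(de), 45)
  expect_equal(nrow(attr(de, "pairs")), 45)
})

test_that("fold-change rule matches hand arithmetic and sign convention", {
  expr <- make_expr(list(g1 = c(1, 7), g2 = c(5, 5), g3 = c(7, 1)))
  de <- call_pairwise_de(expr, de_call_config(log2fc_threshold = 1,
                                              pseudocount = 1))
  # log2((7+1)/(1+1)) = 2 >= 1: up in the later sample
  expect_equal(de["g1", "s01:s02"], 1L)
  expect_equal(de["g2", "s01:s02"], 0L)
  expect_equal(de["g3", "s01:s02"], -1L)
})

test_that("constant genes give all-zero rows and low expression is floored", {
  expr <- make_expr(list(flat = rep(20, 6), faint = c(0.2, 0.9, 0.1, 0.5, 0.3, 0.05)))
  de <- call_pairwise_de(expr)
  expect_true(all(de["flat", ] == 0L))
  expect_true(all(de["faint", ] == 0L))  # below floor in both samples of every pair
})

test_that("reversing sample order flips the ternary signs", {
  set.seed(42)
  expr <- matrix(rlnorm(60, 2, 1), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  de <- call_pairwise_de(expr)
  rev <- call_pairwise_de(expr[, 6:1])
  pr <- attr(rev, "pairs")
  for (p in seq_len(nrow(pr))) {
    orig_col <- paste(pr$j[p], pr$i[p], sep = ":")  # reversed order swaps i/j
    expect_identical(rev[, p], -de[, orig_col])
  }
})

test_that("an unreachable fold-change threshold silences every call", {
  set.seed(1)
  expr <- matrix(rlnorm(40, 2, 2), 8, 5,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  de <- call_pairwise_de(expr, de_call_config(log2fc_threshold = 1e6))
  expect_true(all(de == 0L))
  hk <- housekeeping_genes(expr, de, housekeeping_config(floor = 10))
  expect_setequal(hk, rownames(expr)[rowSums(expr < 10) == 0])
})

test_that("replicate groups gate calls and silence within-group pairs", {
  set.seed(5)
  base <- c(100, 100, 100, 5, 5, 5)
  expr <- rbind(
    strong = base * rlnorm(6, 0, 0.05),
    flat = rep(50, 6) * rlnorm(6, 0, 0.05))
  colnames(expr) <- paste0("s", 1:6)
  groups <- factor(c("A", "A", "A", "B", "B", "B"))
  de <- call_pairwise_de(expr, de_call_config(), groups = groups)
  pr <- attr(de, "pairs")
  within <- groups[match(pr$i, colnames(expr))] ==
            groups[match(pr$j, colnames(expr))]
  expect_true(all(de[, within] == 0L))
  expect_true(all(de["strong", !within] == -1L))
  expect_true(all(de["flat", !within] == 0L))
})

test_that("housekeeping filter applies the floor and the all-zero-row rule", {
  expr <- make_expr(list(
    ok = rep(12, 10),
    dips = c(rep(12, 9), 9.9),
    called = rep(12, 10)))
  de <- call_pairwise_de(expr, de_call_config(log2fc_threshold = 1e6))
  de["called", 3] <- 1L
  expect_identical(housekeeping_genes(expr, de), "ok")
  expect_error(housekeeping_genes(expr[1:2, ], de), "same genes")
})

test_that("regulated set is the union of bicluster gene lists", {
  bc <- function(g) list(genes = g)
  expect_setequal(regulated_genes(list(bc(paste0("a", 1:5)), bc(paste0("b", 1:5)))),
                  c(paste0("a", 1:5), paste0("b", 1:5)))
  expect_equal(length(regulated_genes(list(bc(c("x", "y", "z", "u", "v")),
                                           bc(c("x", "y", "z", "p", "q"))))), 7)
  expect_identical(regulated_genes(list()), character(0))
})

test_that("noise-free simulation recovers housekeeping truth exactly", {
  cfg <- family_sim_config(n_families = 40, regulated_fraction = 0.4,
                           noise_sigma = 0, seed = 21)
  tr <- simulate_families(cfg)
  expr <- simulate_expression(tr)
  de <- call_pairwise_de(expr)
  hk <- housekeeping_genes(expr, de)
  focal <- tr$genes[tr$genes$species == "Ppa", ]
  expect_setequal(hk, focal$gene[!focal$regulated])
})

test_that("stage statistic is 1 for identical stages and exact for the textbook case", {
  expect_equal(stage_specificity_stat(c(1, 2, 3, 1, 2, 3),
                                      rep(c("a", "b"), each = 3)), 1)
  # {1,2,3} vs {10,11,12}: most extreme 3v3 split, p = 2/20
  expect_equal(stage_specificity_stat(c(1, 2, 3, 10, 11, 12),
                                      rep(c("a", "b"), each = 3)), 0.1)
  # max semantics: an identical pair of stages drives the statistic to 1
  vals <- c(1, 2, 3, 50, 60, 70, 1, 2, 3)
  stages <- rep(c("a", "b", "c"), each = 3)
  expect_equal(stage_specificity_stat(vals, stages), 1)
  expect_error(stage_specificity_stat(c(1, 2), factor(c("a", "b"),
                                                      levels = c("a", "b", "c"))),
               "stage|group")
})

test_that("exact rank-sum p equals the enumeration oracle, ties included", {
  set.seed(77)
  for (rep in 1:40) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- if (rep %% 2 == 0) sample(1:6, n1 + n2, replace = TRUE)
            else rnorm(n1 + n2)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(wilcox_ranksum_p(x, y), oracle_wilcox_two_sided(x, y),
                 tolerance = 1e-12)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(wilcox_ranksum_p(x, y),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("sample overview reports correlations, PCA fractions and DE clustering", {
  set.seed(8)
  expr <- matrix(rlnorm(300, 2, 1), 30, 10,
                 dimnames = list(paste0("g", 1:30), sprintf("s%02d", 1:10)))
  expr[, 2] <- expr[, 1]  # duplicate sample
  de <- call_pairwise_de(expr)
  ov <- sample_overview(expr, de)
  expect_equal(ov$spearman["s01", "s02"], 1)
  expect_equal(ov$de_counts["s01", "s02"], 0)
  expect_true(all(diff(ov$pca$variance_fraction) <= 1e-12))
  expect_lte(sum(ov$pca$variance_fraction), 1 + 1e-12)
  # the duplicated pair has distance 0 and merges first
  first <- sort(-ov$dendrogram$merge[1, ])
  expect_identical(ov$dendrogram$labels[first], c("s01", "s02"))
})

test_that("DE-count clustering merges the closest pair first (hand-checked distances)", {
  expr <- matrix(rlnorm(30, 2, 1), 10, 3,
                 dimnames = list(paste0("g", 1:10), c("s1", "s2", "s3")))
  de <- call_pairwise_de(expr, de_call_config(log2fc_threshold = 1e6))
  # plant DE counts: (s1,s2)=0, (s1,s3)=4, (s2,s3)=4
  de[1:4, "s1:s3"] <- 1L
  de[1:4, "s2:s3"] <- 1L
  ov <- sample_overview(expr, de)
  first <- sort(-ov$dendrogram$merge[1, ])
  expect_identical(ov$dendrogram$labels[first], c("s1", "s2"))
  # constant sample flagged as missing correlation
  expr2 <- expr; expr2[, 3] <- 7
  ov2 <- sample_overview(expr2, call_pairwise_de(expr2))
  expect_identical(ov2$constant_samples, "s3")
  expect_true(is.na(ov2$spearman["s1", "s3"]))
})
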