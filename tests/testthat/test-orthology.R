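oc <- orthology_config("Ppa", "Cel")

test_that("config invariants are enforced", {
  expect_error(orthology_config("Ppa", "Cel", panel_species = c("Ppa", "Cel")),
               "focal")
  expect_error(orthology_config("Ppa", "Cel", panel_species = "Cbr"),
               "panel")
  expect_error(orthology_config("Ppa", "Cel", evalue_threshold = 0))
})

test_that("best interspecies score takes the top bitscore with the documented tie-break", {
  hits <- make_hits(
    query = c("Ppa_a", "Ppa_a", "Ppa_b", "Ppa_c", "Ppa_c"),
    subject = c("Cel_x", "Cel_y", "Ppa_c", "Cel_x", "Cel_y"),
    bitscore = c(120, 300, 80, 250, 250),
    evalue = c(1e-12, 1e-30, 1e-8, 1e-60, 1e-80))
  best <- best_interspecies_scores(hits, oc)
  expect_equal(best["Ppa_a", "best_bitscore"], 300)
  expect_equal(best["Ppa_a", "best_subject"], "Cel_y")
  expect_equal(best["Ppa_b", "best_bitscore"], 0)  # no interspecies hit
  expect_true(is.na(best["Ppa_b", "best_subject"]))
  expect_equal(best["Ppa_c", "best_subject"], "Cel_y")  # tie: smaller e-value
})

test_that("inparalog rule compares intraspecies scores to the best interspecies score", {
  hits <- make_hits(
    query = c("Ppa_a", "Ppa_a", "Ppa_b", "Ppa_b"),
    subject = c("Cel_x", "Ppa_b", "Cel_x", "Ppa_a"),
    bitscore = c(250, 300, 250, 200))
  best <- best_interspecies_scores(hits, oc)
  inp <- find_inparalogs(hits, best, oc)
  expect_true(inp$flags[["Ppa_a"]])    # 300 > 250
  expect_false(inp$flags[["Ppa_b"]])   # 200 < 250
  expect_error(find_inparalogs(hits, best, oc, intraspecies_only = TRUE),
               "cross-species")
  # symmetric variant needs the score to beat both genes' best interspecies hits
  sym <- find_inparalogs(hits, best, oc, symmetric = TRUE)
  expect_true(sym$flags[["Ppa_a"]])
})

test_that("one-to-one calls require reciprocity and no inparalog on either side", {
  base <- sym_hits(query = "Ppa_a", subject = "Cel_x", bitscore = 400)
  best <- best_interspecies_scores(base, oc)
  inp <- find_inparalogs(base, best, oc)
  expect_equal(one_to_one_orthologs(best, inp, oc)$focal, "Ppa_a")

  # inparalog on the focal side vetoes the pair
  veto <- rbind(base, make_hits(query = c("Ppa_a", "Ppa_a2"),
                                subject = c("Ppa_a2", "Ppa_a"),
                                bitscore = c(450, 450)))
  class(veto) <- c("similarity_hits", "data.frame")
  bv <- best_interspecies_scores(veto, oc)
  iv <- find_inparalogs(veto, bv, oc)
  expect_equal(nrow(one_to_one_orthologs(bv, iv, oc)), 0)

  # non-reciprocal best hits are rejected
  nonrec <- sym_hits(query = c("Ppa_a", "Ppa_b", "Cel_x"),
                     subject = c("Cel_x", "Cel_x", "Ppa_b"),
                     bitscore = c(300, 400, 400))
  bn <- best_interspecies_scores(nonrec, oc)
  inr <- find_inparalogs(nonrec, bn, oc)
  expect_equal(one_to_one_orthologs(bn, inr, oc)$focal, "Ppa_b")
})

test_that("paralog components label transitive closure of intraspecies hits", {
  hits <- make_hits(query = c("Ppa_a", "Ppa_b"),
                    subject = c("Ppa_b", "Ppa_c"),
                    bitscore = c(100, 100))
  comp <- paralog_components(hits, oc, genes = c("Ppa_a", "Ppa_b", "Ppa_c",
                                                 "Ppa_lone"))
  expect_equal(comp[c("Ppa_a", "Ppa_b", "Ppa_c"), "component_size"],
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(length(unique(comp[c("Ppa_a", "Ppa_b", "Ppa_c"), "component"])), 1)
  expect_equal(comp["Ppa_lone", "component_size"], 1L)
})

test_that("component labelling matches the adjacency-matrix-squaring oracle", {
  set.seed(31)
  genes <- sprintf("Ppa_g%02d", 1:50)
  edges <- cbind(sample(genes, 60, replace = TRUE),
                 sample(genes, 60, replace = TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  hits <- make_hits(query = edges[, 1], subject = edges[, 2],
                    bitscore = rep(100, nrow(edges)))
  comp <- paralog_components(hits, oc, genes = genes)
  oracle <- oracle_components(edges, genes)
  # same partition: equal labels iff equal oracle labels
  for (pair in combn(genes, 2, simplify = FALSE)) {
    expect_equal(comp[pair[1], "component"] == comp[pair[2], "component"],
                 oracle[[pair[1]]] == oracle[[pair[2]]])
  }
})

test_that("classification follows the documented priority rules", {
  # Ppa_a: panel hit + component of 3, not one-to-one -> conserved_multicopy
  # Ppa_d: no panel hit, singleton -> orphan_singleton
  hits <- sym_hits(
    query = c("Ppa_a", "Ppa_a", "Ppa_b", "Cel_x"),
    subject = c("Cel_x", "Ppa_b", "Ppa_c", "Cel_y"),
    bitscore = c(100, 300, 280, 90))
  res <- classify_genes(hits, oc, genes = c("Ppa_a", "Ppa_b", "Ppa_c", "Ppa_d"))
  calls <- setNames(res$calls$class, res$calls$gene)
  expect_equal(calls[["Ppa_a"]], "conserved_multicopy")
  expect_equal(calls[["Ppa_b"]], "orphan_multicopy")
  expect_equal(calls[["Ppa_d"]], "orphan_singleton")
  expect_equal(nrow(res$pairs), 0)  # Ppa_a has an inparalog (300 > 100)
})

test_that("one-to-one genes are excluded before the multicopy subdivision", {
  # Ppa_a <-> Cel_x reciprocal best, no inparalogs (low intra scores);
  # Ppa_b's only paralog partner is the one-to-one gene Ppa_a
  hits <- sym_hits(
    query = c("Ppa_a", "Ppa_a", "Ppa_b"),
    subject = c("Cel_x", "Ppa_b", "Cel_x"),
    bitscore = c(400, 50, 100))
  res <- classify_genes(hits, oc)
  calls <- setNames(res$calls$class, res$calls$gene)
  expect_equal(calls[["Ppa_a"]], "one_to_one")
  expect_equal(calls[["Ppa_b"]], "conserved_singleton")
  expect_false(res$calls$has_inparalog[res$calls$gene == "Ppa_a"])
})

test_that("noise-free simulated families are classified exactly as the truth table", {
  for (s in 1:4) {
    cfg <- family_sim_config(n_families = 8,
                             dup_rate_focal = c(0, 0.8, 1.5, 0.5)[s],
                             dup_rate_other = c(0.5, 0, 1, 1.5)[s],
                             orphan_fraction = c(0, 0.5, 0.3, 1)[s],
                             seed = 40 + s)
    tr <- simulate_families(cfg)
    hits <- simulate_similarity(tr)
    focal <- tr$genes[tr$genes$species == "Ppa", ]
    res <- classify_genes(hits, oc, genes = focal$gene)
    expect_identical(res$calls$class[match(focal$gene, res$calls$gene)],
                     focal$class)
  }
})

test_that("one-to-one pair set is invariant under swapping species roles", {
  cfg <- family_sim_config(n_families = 30, dup_rate_focal = 0.7,
                           dup_rate_other = 0.7, orphan_fraction = 0.2,
                           noise_sigma = 0, seed = 17)
  tr <- simulate_families(cfg)
  hits <- simulate_similarity(tr, similarity_score_params(noise = 0.1))
  res_f <- classify_genes(hits, orthology_config("Ppa", "Cel"))
  res_r <- classify_genes(hits, orthology_config("Cel", "Ppa"))
  fwd <- paste(res_f$pairs$focal, res_f$pairs$comparison)
  rev <- paste(res_r$pairs$comparison, res_r$pairs$focal)
  expect_setequal(fwd, rev)
})

test_that("tightening the e-value threshold never grows components or the conserved set", {
  cfg <- family_sim_config(n_families = 40, seed = 23)
  tr <- simulate_families(cfg)
  hits <- simulate_similarity(tr, similarity_score_params(noise = 0.3))
  genes <- tr$genes$gene[tr$genes$species == "Ppa"]
  prev_cons <- NULL; prev_sizes <- NULL
  for (thr in c(1e-3, 1e-8, 1e-12)) {
    cfg_t <- orthology_config("Ppa", "Cel", evalue_threshold = thr)
    res <- classify_genes(hits, cfg_t, genes = genes)
    # homolog status and raw paralog-graph components shrink monotonically
    cons <- res$calls$gene[grepl("conserved|one_to_one", res$calls$class)]
    comp <- paralog_components(hits, cfg_t, genes = genes)
    sizes <- setNames(comp$component_size, comp$gene)
    if (!is.null(prev_cons)) {
      expect_true(all(cons %in% prev_cons))
      expect_true(all(sizes[genes] <= prev_sizes[genes]))
    }
    prev_cons <- cons; prev_sizes <- sizes
  }
})

test_that("curated evaluation counts the confusion cells and unassessable genes", {
  base <- sym_hits(query = c("Ppa_a", "Ppa_b", "Ppa_c"),
                   subject = c("Cel_x", "Cel_y", "Cel_z"),
                   bitscore = c(400, 380, 360))
  # Cel_z's best focal hit is Ppa_d, whose inparalog Ppa_e vetoes the pair,
  # so Cel_z stays unpredicted (and Ppa_c is not reciprocal)
  extra <- sym_hits(query = c("Ppa_d", "Ppa_d"),
                    subject = c("Cel_z", "Ppa_e"),
                    bitscore = c(390, 450))
  hits <- rbind(base, extra)
  class(hits) <- c("similarity_hits", "data.frame")
  res <- classify_genes(hits, oc)
  curated <- data.frame(
    gene = c("Cel_x", "Cel_y", "Cel_z", "Cel_u", "Cel_v"),
    has_one_to_one = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  ev <- evaluate_against_curated(res, curated)
  expect_equal(ev$tp, 2)            # Cel_x, Cel_y predicted
  expect_equal(ev$fn, 1)            # Cel_z manual-positive, not predicted
  expect_equal(ev$unassessable, 2)  # Cel_u, Cel_v outside the hit universe
  expect_equal(ev$sensitivity, 2 / 3)

  # perfect predictor on simulated truth: off-diagonal zero
  cfg <- family_sim_config(n_families = 25, orphan_fraction = 0.2, seed = 19)
  tr <- simulate_families(cfg)
  sim_hits <- simulate_similarity(tr)
  sim_res <- classify_genes(sim_hits, oc)
  other <- tr$genes[tr$genes$species == "Cel", ]
  fam_oto <- tr$families$family[tr$families$n_focal == 1 &
                                tr$families$n_other == 1]
  cur <- data.frame(gene = other$gene,
                    has_one_to_one = other$family %in% fam_oto)
  ev2 <- evaluate_against_curated(sim_res, cur)
  expect_equal(ev2$fn, 0)
  expect_equal(ev2$fp, 0)
})
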