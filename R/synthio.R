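#' Configuration for the two-species gene-family simulator
#'
#' Describes a simulated comparison between a focal species and one
#' comparison species: how many gene families to draw, how often each lineage
#' duplicates, how many families are orphans (undetectable outside the focal
#' lineage), and how developmental regulation is distributed over families.
#'
#' The copy-number model is deliberately minimal: each lineage carries
#' `1 + Poisson(dup_rate)` copies of every non-orphan family, all duplications
#' post-dating the speciation, with gene loss folded into `orphan_fraction`.
#' Regulation is Bernoulli per family; for families with more than one focal
#' copy the odds of being regulated are multiplied by
#' `multicopy_regulation_boost`. Regulated families follow one stage-specific
#' expression archetype (high in one stage group, baseline elsewhere);
#' unregulated families are flat "housekeeping" profiles.
#'
#' @param n_families number of gene families to simulate.
#' @param dup_rate_focal expected number of post-speciation duplications per
#'   family on the focal lineage (Poisson mean).
#' @param dup_rate_other same for the comparison lineage.
#' @param orphan_fraction probability that a family has no detectable member
#'   outside the focal species.
#' @param regulated_fraction baseline probability that a single-copy family is
#'   developmentally regulated.
#' @param multicopy_regulation_boost multiplicative increase of the regulation
#'   odds for families with >1 focal copy (>= 1; 1 means no association).
#' @param n_samples number of expression samples (default 10).
#' @param stage_assignment factor (or character) of length `n_samples` mapping
#'   each sample to a stage group. Default: three groups ("early", "dauer",
#'   "late") covering samples 1-3, 4-6 and 7-10 of a ten-sample timecourse.
#' @param noise_sigma standard deviation of multiplicative log-normal
#'   expression noise (log scale).
#' @param expr_base,expr_high baseline and stage-elevated expression level of
#'   regulated archetypes (FPKM-like units).
#' @param hk_level flat expression level of unregulated families; must be at
#'   least `hk_floor`.
#' @param hk_floor the housekeeping expression floor the simulation guarantees
#'   for unregulated families in the noise-free limit (default 10).
#' @param focal_species,other_species species tags used in gene identifiers.
#' @param seed integer seed; identical seed and config give byte-identical
#'   simulation output.
#' @return an object of class `family_sim_config` (a validated list).
#' @export
family_sim_config <- function(n_families = 100,
                              dup_rate_focal = 0.5,
                              dup_rate_other = 0.5,
                              orphan_fraction = 0.32,
                              regulated_fraction = 0.17,
                              multicopy_regulation_boost = 3,
                              n_samples = 10,
                              stage_assignment = NULL,
                              noise_sigma = 0.15,
                              expr_base = 5,
                              expr_high = 50,
                              hk_level = 40,
                              hk_floor = 10,
                              focal_species = "Ppa",
                              other_species = "Cel",
                              seed = 1L) {
  chk_num <- function(x, nm, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi)
      stop_devodup(sprintf("'%s' must be a finite number in [%s, %s]", nm, lo, hi))
    x
  }
  n_families <- as.integer(chk_num(n_families, "n_families", 1))
  dup_rate_focal <- chk_num(dup_rate_focal, "dup_rate_focal")
  dup_rate_other <- chk_num(dup_rate_other, "dup_rate_other")
  orphan_fraction <- chk_num(orphan_fraction, "orphan_fraction", 0, 1)
  regulated_fraction <- chk_num(regulated_fraction, "regulated_fraction", 0, 1)
  multicopy_regulation_boost <-
    chk_num(multicopy_regulation_boost, "multicopy_regulation_boost", 1)
  n_samples <- as.integer(chk_num(n_samples, "n_samples", 2))
  noise_sigma <- chk_num(noise_sigma, "noise_sigma")
  expr_base <- chk_num(expr_base, "expr_base")
  expr_high <- chk_num(expr_high, "expr_high")
  hk_floor <- chk_num(hk_floor, "hk_floor", 1e-12)
  hk_level <- chk_num(hk_level, "hk_level", hk_floor)

  if (is.null(stage_assignment)) {
    stage_assignment <- default_stage_assignment(n_samples)
  }
  stage_assignment <- as.factor(stage_assignment)
  if (length(stage_assignment) != n_samples)
    stop_devodup("'stage_assignment' must label every sample (length n_samples)")
  if (anyNA(stage_assignment))
    stop_devodup("'stage_assignment' must not contain NA: stage groups must partition the samples")
  if (nlevels(droplevels(stage_assignment)) < 2)
    stop_devodup("at least two stage groups are required")
  if (is.null(names(stage_assignment)))
    names(stage_assignment) <- sprintf("s%02d", seq_len(n_samples))
  if (identical(focal_species, other_species))
    stop_devodup("focal and comparison species tags must differ")

  structure(list(
    n_families = n_families,
    dup_rate_focal = dup_rate_focal,
    dup_rate_other = dup_rate_other,
    orphan_fraction = orphan_fraction,
    regulated_fraction = regulated_fraction,
    multicopy_regulation_boost = multicopy_regulation_boost,
    n_samples = n_samples,
    stage_assignment = droplevels(stage_assignment),
    noise_sigma = noise_sigma,
    expr_base = expr_base,
    expr_high = expr_high,
    hk_level = hk_level,
    hk_floor = hk_floor,
    focal_species = focal_species,
    other_species = other_species,
    seed = as.integer(seed)
  ), class = "family_sim_config")
}

# Three roughly equal, ordered stage groups; for the canonical ten-sample
# timecourse this is early larvae (3), dauer (3), late larvae + adults (4).
default_stage_assignment <- function(n_samples) {
  groups <- c("early", "dauer", "late")
  sizes <- diff(round(seq(0, n_samples, length.out = 4)))
  f <- factor(rep(groups, times = sizes), levels = groups)
  names(f) <- sprintf("s%02d", seq_len(n_samples))
  f
}

#' Simulate two-species gene families with known orthology ground truth
#'
#' Draws `n_families` families under the birth model of
#' [family_sim_config()]. Each lineage receives `1 + Poisson(dup_rate)`
#' copies; orphan families have no comparison-species member. Every focal
#' gene is labelled with its true orthology class, determined by the realized
#' family topology:
#'
#' * one focal and one comparison copy: `one_to_one`;
#' * one focal copy, several comparison copies: `conserved_singleton`;
#' * several focal copies, any comparison copies: `conserved_multicopy`;
#' * orphan family with one / several focal copies: `orphan_singleton` /
#'   `orphan_multicopy`.
#'
#' Duplication times (uniform between 0.2 and 0.9 time units before present,
#' speciation at 1.0) are recorded per gene and drive
#' [simulate_similarity()]; they make every within-species family pair more
#' similar than any cross-species pair, i.e. all simulated duplicates are
#' inparalogs with respect to the speciation.
#'
#' @param config a [family_sim_config()].
#' @return an object of class `family_truth`: a list with `genes` (data frame
#'   of gene, species, family, class, regulated, archetype, birth_time),
#'   `families` (per-family summary) and the `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  with_local_seed(config$seed, {
    nf <- config$n_families
    orphan <- runif(nf) < config$orphan_fraction
    n_focal <- 1L + rpois(nf, config$dup_rate_focal)
    n_other <- ifelse(orphan, 0L, 1L + rpois(nf, config$dup_rate_other))
    multicopy <- n_focal > 1L

    odds <- config$regulated_fraction / max(1 - config$regulated_fraction, 1e-12)
    p_reg <- ifelse(multicopy,
                    odds * config$multicopy_regulation_boost /
                      (1 + odds * config$multicopy_regulation_boost),
                    config$regulated_fraction)
    if (config$regulated_fraction >= 1) p_reg[] <- 1
    regulated <- runif(nf) < p_reg

    stages <- levels(config$stage_assignment)
    archetype <- ifelse(regulated,
                        paste0(sample(stages, nf, replace = TRUE), "_high"),
                        "flat")

    fam_ids <- sprintf("fam%04d", seq_len(nf))
    gene_rows <- vector("list", nf)
    for (f in seq_len(nf)) {
      mk <- function(species, n) {
        if (n == 0L) return(NULL)
        # copy 1 is the lineage trunk (present at speciation); extra copies
        # branch off at their duplication time before present
        bt <- c(0, if (n > 1L) sort(runif(n - 1L, 0.2, 0.9)))
        data.frame(
          gene = sprintf("%s-%s-g%d", species, fam_ids[f], seq_len(n)),
          species = species,
          family = fam_ids[f],
          birth_time = bt,
          stringsAsFactors = FALSE
        )
      }
      gene_rows[[f]] <- rbind(mk(config$focal_species, n_focal[f]),
                              mk(config$other_species, n_other[f]))
    }
    genes <- do.call(rbind, gene_rows)
    rownames(genes) <- NULL

    fam_class <- ifelse(orphan,
                        ifelse(multicopy, "orphan_multicopy", "orphan_singleton"),
                        ifelse(multicopy, "conserved_multicopy",
                               ifelse(n_other == 1L, "one_to_one", "conserved_singleton")))
    idx <- match(genes$family, fam_ids)
    genes$class <- ifelse(genes$species == config$focal_species, fam_class[idx], NA)
    genes$regulated <- regulated[idx]
    genes$archetype <- archetype[idx]

    families <- data.frame(
      family = fam_ids, n_focal = n_focal, n_other = n_other,
      orphan = orphan, multicopy = multicopy,
      regulated = regulated, archetype = archetype,
      stringsAsFactors = FALSE
    )
    structure(list(genes = genes, families = families, config = config),
              class = "family_truth")
  })
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("family_truth: %d families, %d genes (%d focal '%s')\n",
              nrow(x$families), nrow(x$genes),
              sum(x$genes$species == x$config$focal_species),
              x$config$focal_species))
  print(table(class = x$genes$class[!is.na(x$genes$class)]))
  invisible(x)
}

#' Similarity-score model parameters for [simulate_similarity()]
#'
#' Bit scores decay exponentially in divergence time, `bitscore = S0 *
#' exp(-k * t)`, and e-values are a fixed monotone map of the bit score
#' (`evalue = 10^(-bitscore / 10)`). Any strictly monotone map would do: the
#' downstream orthology rules are rank-based.
#'
#' @param S0 bit score at zero divergence.
#' @param k exponential decay rate per divergence time unit.
#' @param noise standard deviation of multiplicative log-normal score noise
#'   applied independently to each directed hit (0 = deterministic scores).
#' @param min_bitscore detectability floor; directed hits scoring below it are
#'   omitted from the output, emulating BLAST's reporting cutoff.
#' @param cross_family_depth divergence time separating genes of different
#'   families (deep enough that cross-family hits fall below `min_bitscore`
#'   under the defaults).
#' @return a list of class `similarity_score_params`.
#' @export
similarity_score_params <- function(S0 = 500, k = 2, noise = 0,
                                    min_bitscore = 50, cross_family_depth = 3) {
  stopifnot(S0 > 0, k > 0, noise >= 0, min_bitscore >= 0, cross_family_depth > 1)
  structure(list(S0 = S0, k = k, noise = noise, min_bitscore = min_bitscore,
                 cross_family_depth = cross_family_depth),
            class = "similarity_score_params")
}

#' Simulate an all-vs-all protein similarity table from simulated families
#'
#' Emits directed hits (both query->subject directions) for every gene pair
#' whose modelled bit score passes the detectability floor. Divergence times
#' follow the family topology recorded by [simulate_families()]: two
#' same-species family members diverge at the later of their duplication
#' times, any cross-species family pair diverges at the speciation (t = 1),
#' and genes of different families sit at `cross_family_depth`. Bit scores
#' are therefore strictly decreasing in divergence (up to optional noise),
#' which is all the rank-based orthology rules require.
#'
#' @param truth a `family_truth` object.
#' @param score_params a [similarity_score_params()].
#' @return a `similarity_hits` data frame (columns query, subject, evalue,
#'   bitscore, query_species, subject_species), as produced by
#'   [read_similarity_table()].
#' @export
simulate_similarity <- function(truth, score_params = similarity_score_params()) {
  stopifnot(inherits(truth, "family_truth"),
            inherits(score_params, "similarity_score_params"))
  p <- score_params
  genes <- truth$genes
  with_local_seed(truth$config$seed + 1L, {
    rows <- vector("list", nrow(truth$families))
    for (f in seq_len(nrow(truth$families))) {
      g <- genes[genes$family == truth$families$family[f], , drop = FALSE]
      n <- nrow(g)
      if (n < 2L) { rows[[f]] <- NULL; next }
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      i <- pairs[, 1]; j <- pairs[, 2]
      same_sp <- g$species[i] == g$species[j]
      t <- ifelse(same_sp, pmax(g$birth_time[i], g$birth_time[j]), 1.0)
      base <- p$S0 * exp(-p$k * t)
      # one noise draw per direction: BLAST scores are not exactly symmetric
      bs_fwd <- base * if (p$noise > 0) exp(rnorm(length(base), 0, p$noise)) else 1
      bs_rev <- base * if (p$noise > 0) exp(rnorm(length(base), 0, p$noise)) else 1
      rows[[f]] <- data.frame(
        query = c(g$gene[i], g$gene[j]),
        subject = c(g$gene[j], g$gene[i]),
        bitscore = c(bs_fwd, bs_rev),
        query_species = c(g$species[i], g$species[j]),
        subject_species = c(g$species[j], g$species[i]),
        stringsAsFactors = FALSE
      )
    }
    # cross-family pairs only materialize if the depth could clear the floor
    if (p$S0 * exp(-p$k * p$cross_family_depth) * exp(4 * p$noise) >= p$min_bitscore) {
      rows <- c(rows, list(cross_family_hits(genes, p)))
    }
    hits <- do.call(rbind, rows)
    if (is.null(hits))
      hits <- data.frame(query = character(0), subject = character(0),
                         bitscore = numeric(0), query_species = character(0),
                         subject_species = character(0),
                         stringsAsFactors = FALSE)
    hits <- hits[hits$bitscore >= p$min_bitscore, , drop = FALSE]
    hits$evalue <- 10^(-hits$bitscore / 10)
    hits <- hits[order(hits$query, hits$subject),
                 c("query", "subject", "evalue", "bitscore",
                   "query_species", "subject_species")]
    rownames(hits) <- NULL
    class(hits) <- c("similarity_hits", "data.frame")
    hits
  })
}

cross_family_hits <- function(genes, p) {
  n <- nrow(genes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- genes$family[i] != genes$family[j]
  i <- i[keep]; j <- j[keep]
  base <- p$S0 * exp(-p$k * p$cross_family_depth)
  bs_fwd <- base * if (p$noise > 0) exp(rnorm(length(i), 0, p$noise)) else rep(1, length(i))
  bs_rev <- base * if (p$noise > 0) exp(rnorm(length(i), 0, p$noise)) else rep(1, length(i))
  data.frame(
    query = c(genes$gene[i], genes$gene[j]),
    subject = c(genes$gene[j], genes$gene[i]),
    bitscore = c(bs_fwd, bs_rev),
    query_species = c(genes$species[i], genes$species[j]),
    subject_species = c(genes$species[j], genes$species[i]),
    stringsAsFactors = FALSE
  )
}

#' Simulate stage-structured expression for the focal genes of a simulation
#'
#' Every regulated family follows its stage archetype: expression `expr_high`
#' in the archetype's stage group and `expr_base` elsewhere, shared by all
#' family members. Unregulated families are flat at `hk_level` (>= the
#' housekeeping floor) in every sample. Independent multiplicative log-normal
#' noise of standard deviation `noise_sigma` is applied per gene and sample;
#' with `noise_sigma = 0` family members have identical profiles and every
#' unregulated gene passes the housekeeping filter by construction.
#'
#' @param truth a `family_truth` object.
#' @param config simulation config; defaults to the one stored in `truth`.
#' @return a numeric genes x samples matrix (focal-species genes only) with
#'   the stage assignment attached as attribute `"stages"`.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "family_truth"), inherits(config, "family_sim_config"))
  stages <- config$stage_assignment
  if (length(stages) != config$n_samples)
    stop_devodup("stage_assignment does not cover all samples")
  focal <- truth$genes[truth$genes$species == config$focal_species, , drop = FALSE]
  samples <- names(stages)
  with_local_seed(config$seed + 2L, {
    profile_for <- function(arch) {
      if (arch == "flat") return(rep(config$hk_level, length(stages)))
      grp <- sub("_high$", "", arch)
      ifelse(as.character(stages) == grp, config$expr_high, config$expr_base)
    }
    base <- t(vapply(focal$archetype, profile_for, numeric(length(stages))))
    noise <- if (config$noise_sigma > 0)
      matrix(rlnorm(length(base), 0, config$noise_sigma), nrow = nrow(base))
    else 1
    expr <- base * noise
    dimnames(expr) <- list(focal$gene, samples)
    attr(expr, "stages") <- stages
    expr
  })
}

#' Ternary matrix with planted sign-consistent blocks
#'
#' Builds a genes x comparisons matrix in \{-1, 0, +1\} with sparse random
#' background and `n_blocks` planted blocks of coherent sign, the benchmark
#' regime for bicluster recovery: disjoint gene and comparison strata, a
#' random sign per block comparison, each block entry agreeing with the block
#' sign with probability `agreement` (and drawn from the background model
#' otherwise), background entries nonzero with probability `background_rate`
#' (equal chance of either sign).
#'
#' @param n_genes,n_comparisons matrix dimensions.
#' @param n_blocks,block_genes,block_comparisons number and size of planted
#'   blocks; `n_blocks * block_genes <= n_genes` and likewise for comparisons.
#' @param agreement probability a block entry equals the block sign.
#' @param background_rate probability a background entry is nonzero.
#' @param seed integer seed.
#' @return a list with `matrix` (dimnamed integer matrix) and `blocks`, a list
#'   of per-block gene ids, comparison ids and signs.
#' @export
plant_ternary_blocks <- function(n_genes = 1000, n_comparisons = 45,
                                 n_blocks = 5, block_genes = 40,
                                 block_comparisons = 8,
                                 agreement = 0.9, background_rate = 0.05,
                                 seed = 1L) {
  stopifnot(n_blocks * block_genes <= n_genes,
            n_blocks * block_comparisons <= n_comparisons,
            agreement >= 0, agreement <= 1,
            background_rate >= 0, background_rate <= 1)
  with_local_seed(seed, {
    draw_bg <- function(n) {
      nz <- runif(n) < background_rate
      ifelse(nz, sample(c(-1L, 1L), n, replace = TRUE), 0L)
    }
    m <- matrix(draw_bg(n_genes * n_comparisons), n_genes, n_comparisons,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("c%02d", seq_len(n_comparisons))))
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      gi <- (b - 1L) * block_genes + seq_len(block_genes)
      ci <- (b - 1L) * block_comparisons + seq_len(block_comparisons)
      signs <- sample(c(-1L, 1L), block_comparisons, replace = TRUE)
      agree <- matrix(runif(block_genes * block_comparisons) < agreement,
                      block_genes, block_comparisons)
      block <- matrix(rep(signs, each = block_genes),
                      block_genes, block_comparisons)
      bg <- matrix(draw_bg(block_genes * block_comparisons),
                   block_genes, block_comparisons)
      m[gi, ci] <- ifelse(agree, block, bg)
      blocks[[b]] <- list(genes = rownames(m)[gi], comparisons = colnames(m)[ci],
                          signs = setNames(signs, colnames(m)[ci]))
    }
    list(matrix = m, blocks = blocks)
  })
}
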