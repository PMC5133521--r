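#' Simulate a complete admixed family study
#'
#' One call producing pedigrees, genotypes with known local ancestry, and
#' (optionally) phenotypes under the package's standard study conditions.
#'
#' @param n_pedigrees,generations,sibship family structure (see
#'   [simulate_pedigrees()])
#' @param n_variants number of variants
#' @param pop_labels,fst populations and Balding-Nichols differentiation
#' @param alpha Dirichlet admixture concentration
#' @param maf_spectrum ancestral-frequency spectrum
#' @param length_cM chromosome map length (linked mode)
#' @param linkage tract-based recombination (`TRUE`) or fully independent
#'   markers (`FALSE`)
#' @param pheno_cfg optional [phenotype_config()] to also simulate traits
#' @param seed master seed; stage seeds are derived deterministically
#' @return list: `ped`, `freqs`, `map`, `genotypes`, `ancestry`,
#'   `haplotypes`, `founder_q`, and `phenotypes` when requested
#' @export
simulate_family_study <- function(n_pedigrees = 20, generations = 3, sibship = 3,
                                  n_variants = 20000,
                                  pop_labels = c("POP1", "POP2"),
                                  fst = c(0.1, 0.1), alpha = c(3, 1),
                                  maf_spectrum = maf_uniform(0.05, 0.5),
                                  length_cM = 100, linkage = TRUE,
                                  pheno_cfg = NULL, seed = 1) {
  seeds <- derive_seeds(seed, c("freqs", "ped", "map", "founders", "drop", "pheno"))
  freqs <- simulate_frequencies(n_variants, pop_labels, fst, maf_spectrum,
                                seed = seeds[["freqs"]])
  ped <- simulate_pedigrees(n_pedigrees, generations, sibship, seed = seeds[["ped"]])
  map <- simulate_variant_map(n_variants, length_cM = length_cM,
                              seed = seeds[["map"]])
  admix <- admixture_config(alpha)
  founders <- simulate_founder_haplotypes(ped, freqs, admix, map,
                                          linkage = linkage,
                                          seed = seeds[["founders"]])
  dropped <- drop_genes(ped, founders, seed = seeds[["drop"]])
  out <- list(ped = ped, freqs = freqs, map = map,
              genotypes = dropped$genotypes, ancestry = dropped$ancestry,
              haplotypes = dropped$haplotypes, founder_q = founders$q)
  if (!is.null(pheno_cfg))
    out$phenotypes <- simulate_phenotypes(dropped$genotypes, dropped$ancestry,
                                          ped, pheno_cfg, seed = seeds[["pheno"]])
  out
}

# deterministic per-stage seeds from one master seed (stage-name hashing,
# kept below 2^31)
derive_seeds <- function(master, stages) {
  h <- vapply(stages, function(s) {
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 10000L
  }, numeric(1))
  setNames(as.integer((as.numeric(master) * 10007 + h * 101) %% 2147483629), stages)
}

#' Relationship-classification benchmark on simulated admixed families
#'
#' The package's standard kinship benchmark: simulate admixed
#' three-generation pedigrees genotyped on independent common SNPs, apply
#' the common-variant (Selective) design, estimate kinship with the
#' requested estimators, classify every evaluated pair by rounding to the
#' nearest expected kinship, and tabulate correct-classification rates per
#' true degree. All within-pedigree pairs are evaluated; cross-pedigree
#' (unrelated) pairs are a seeded random subsample of size
#' `n_unrelated_pairs`, so the unrelated rate is a sampled estimate.
#'
#' @param seed master seed
#' @param estimators subset of `c("mle", "pcrelate", "king", "mom")`
#' @param n_pedigrees,generations,sibship,n_variants,fst,alpha study
#'   conditions (defaults: 20 pedigrees, ~340 subjects, 20,000 SNPs, two
#'   populations at Fst 0.1, Dirichlet(3, 1) admixture)
#' @param maf_min Selective-design MAF cutoff
#' @param n_unrelated_pairs cross-pedigree pairs to sample
#' @param n_pcs PCs for the PC-adjusted estimator
#' @return list: `rates` (long data frame: estimator, degree, n_pairs,
#'   rate), `kinship` tables, `n_subjects`, `n_markers`
#' @export
kinship_classification_benchmark <- function(seed = 1,
                                             estimators = c("mle", "pcrelate"),
                                             n_pedigrees = 20, generations = 3,
                                             sibship = 3, n_variants = 20000,
                                             fst = c(0.1, 0.1), alpha = c(3, 1),
                                             maf_min = 0.05,
                                             n_unrelated_pairs = 3000,
                                             n_pcs = 2) {
  sim <- simulate_family_study(n_pedigrees = n_pedigrees,
                               generations = generations, sibship = sibship,
                               n_variants = n_variants, fst = fst,
                               alpha = alpha,
                               maf_spectrum = maf_uniform(0.05, 0.5),
                               linkage = FALSE, seed = seed)
  g <- sim$genotypes
  stats <- compute_variant_stats(g, sim$ped)
  sel <- design_selective(stats, maf_min = maf_min)
  gsel <- subset_variants(g, sel$kept)

  Phi <- pedigree_kinship(sim$ped)
  ids <- rownames(g$dosage)
  n <- length(ids)
  fam <- sim$ped$family[match(ids, sim$ped$id)]
  ap <- all_pairs(n)
  within <- fam[ap[, 1]] == fam[ap[, 2]]
  cross_idx <- which(!within)
  samp <- with_seed(derive_seeds(seed, "pairs")[[1]], {
    sample(cross_idx, min(n_unrelated_pairs, length(cross_idx)))
  })
  pairs <- ap[sort(c(which(within), samp)), , drop = FALSE]
  truth <- true_degree(Phi[cbind(match(ids[pairs[, 1]], rownames(Phi)),
                                 match(ids[pairs[, 2]], rownames(Phi)))])

  kin <- list()
  if ("king" %in% estimators) kin$king <- king_robust(gsel, pairs)
  if ("mom" %in% estimators) kin$mom <- mom_ibd(gsel, pairs = pairs)
  if ("mle" %in% estimators) kin$mle <- mle_ibd_em(gsel, pairs = pairs)
  if ("pcrelate" %in% estimators) {
    part <- pcair_partition(Phi[ids, ids])
    pcs <- pcair_scores(gsel, part$unrelated, n_pcs = n_pcs)
    kin$pcrelate <- pcrelate(gsel, pcs$scores, part$unrelated,
                             n_pcs = n_pcs, pairs = pairs)
  }
  rates <- do.call(rbind, lapply(names(kin), function(est) {
    called <- classify_relationship(pmax(kin[[est]]$kinship, 0))
    tab <- classification_table(truth, called)
    tab$estimator <- est
    tab
  }))
  list(rates = rates, kinship = kin, truth = truth, pairs = pairs,
       n_subjects = n, n_markers = length(sel$kept))
}
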