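trio_ped <- function() {
  pedigree(id = c("F", "M", "C"), family = "T",
           father = c(NA, NA, "F"), mother = c(NA, NA, "M"), sex = c(1, 2, 1))
}

test_that("pedigree kinship reproduces textbook values", {
  ped <- simulate_pedigrees(1, generations = 4, sibship = 2, seed = 1)
  Phi <- pedigree_kinship(ped)
  expect_true(all(diag(Phi) == 0.5))                 # outbred self-kinship
  # founders mutually unrelated
  fo <- ped$id[is_founder(ped)]
  off <- Phi[fo, fo]; diag(off) <- 0
  expect_true(all(off == 0))
  # parent-offspring
  child <- ped$id[!is.na(ped$father)][1]
  expect_equal(Phi[child, ped$father[ped$id == child]], 0.25)
  # first cousins via hand recursion through shared grandparents:
  # phi = 0.0625 must appear in a 3+ generation family with 2 sibships
  expect_true(any(Phi == 0.0625))
  # degrees present: 1st..4th
  expect_setequal(intersect(unique(true_degree(Phi[upper.tri(Phi)])),
                            c("1st", "2nd", "3rd", "4th")),
                  c("1st", "2nd", "3rd", "4th"))
  # cycle detection
  expect_error(pedigree(id = c("A", "B"), family = "F",
                        father = c("B", "A"), mother = c(NA, NA),
                        sex = c(1, 1)), "cycle")
})

test_that("KING-robust matches hand counts and known relationships", {
  # identical vectors with heterozygotes -> exactly 0.5
  g <- toy_geno(rbind(c(0L, 1L, 2L, 1L, 0L), c(0L, 1L, 2L, 1L, 0L)))
  expect_equal(king_robust(g)$kinship, 0.5)
  # the worked example: phi = 1/2 + (4 - 8 - 3 - 2)/8 = -0.625
  g2 <- toy_geno(rbind(c(1L, 1L, 0L, 2L, 1L), c(1L, 2L, 2L, 0L, 1L)))
  expect_equal(king_robust(g2)$kinship, -0.625)
  expect_equal(king_robust(g2, denominator = "sum")$kinship,
               0.5 + (4 - 8 - 3 - 2) / (2 * (3 + 2)))
  # no heterozygote in one member -> undefined
  g3 <- toy_geno(rbind(c(0L, 0L, 2L), c(0L, 1L, 2L)))
  expect_true(is.na(king_robust(g3)$kinship))

  # simulated parent-offspring pairs on common SNPs: mean ~ 0.25
  sim <- simulate_family_study(n_pedigrees = 25, generations = 2, sibship = 1,
                               n_variants = 4000, fst = c(0.01, 0.01),
                               alpha = c(1, 1), linkage = FALSE, seed = 9)
  kin <- king_robust(sim$genotypes)
  Phi <- pedigree_kinship(sim$ped)
  truth <- Phi[cbind(kin$i, kin$j)]
  po <- kin$kinship[truth == 0.25]
  expect_lt(abs(mean(po) - 0.25), 0.01)
})

test_that("method-of-moments IBD recovers duplicates and unrelated pairs", {
  # duplicates: k2 ~ 1, phi ~ 0.5
  withr::with_seed(3, {
    x <- rbinom(4000, 2, runif(4000, 0.1, 0.5))
    g <- toy_geno(rbind(x, x, rbinom(4000, 2, 0.3)))
  })
  kin <- mom_ibd(g, pairs = cbind(1L, 2L))
  expect_gt(kin$k2, 0.95)
  expect_lt(abs(kin$kinship - 0.5), 0.02)

  # P(IBS0 | IBD0) at p = 0.5 equals 2 p^2 q^2 = 0.125, by enumerating the
  # 9 genotype-pair probabilities
  p <- 0.5; gp <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  ibs0 <- gp[1] * gp[3] + gp[3] * gp[1]
  expect_equal(ibs0, 0.125)

  # homogeneous-population unrelated pairs: mean phi ~ 0
  sim <- simulate_family_study(n_pedigrees = 40, generations = 2, sibship = 1,
                               n_variants = 4000, fst = c(0.01, 0.01),
                               alpha = c(1, 1), linkage = FALSE, seed = 10)
  kin2 <- mom_ibd(sim$genotypes)
  truth <- pedigree_kinship(sim$ped)[cbind(kin2$i, kin2$j)]
  # small positive bias from the clamp-and-renormalize step is expected
  expect_lt(abs(mean(kin2$kinship[truth == 0])), 0.01)
})

test_that("EM-MLE is monotone, matches the R reference and the grid oracle", {
  withr::with_seed(11, {
    p <- runif(500, 0.1, 0.5)
    # full-sib-like pair: simulate from k = (0.25, 0.5, 0.25)
    d <- sample(0:2, 500, TRUE, prob = c(0.25, 0.5, 0.25))
    gi <- rbinom(500, 2, p)
    gj <- integer(500)
    for (s in 1:500) {
      shared <- d[s]
      hap_i <- c(rbinom(1, 1, p[s]), rbinom(1, 1, p[s]))
      if (gi[s] == 0) hap_i <- c(0L, 0L) else if (gi[s] == 2) hap_i <- c(1L, 1L)
      else hap_i <- c(1L, 0L)
      new <- rbinom(2, 1, p[s])
      gj[s] <- switch(shared + 1L, sum(new), hap_i[1] + new[1], sum(hap_i))
    }
  })
  ref <- ref_em(gi, gj, p)
  expect_true(all(diff(ref$trace) >= -1e-9))          # EM monotonicity
  g <- toy_geno(rbind(gi, gj))
  fit <- mle_ibd_em(g, freqs = p, pairs = cbind(1L, 2L))
  # accelerated and plain EM stop at slightly different points near the
  # optimum; both must sit on the same maximizer to grid accuracy
  expect_equal(c(fit$k0, fit$k1, fit$k2), ref$k, tolerance = 2e-3)
  # grid-search oracle at 0.01 resolution over the simplex
  grid <- grid_mle(gi, gj, p, res = 0.01)
  ll_fit <- ref_loglik(c(fit$k0, fit$k1, fit$k2), ref_pair_lik(gi, gj, p))
  expect_gte(ll_fit, grid$loglik - 1e-6)
  expect_lt(max(abs(c(fit$k0, fit$k1, fit$k2) - grid$k)), 0.02)
})

test_that("EM-MLE recovers Mendelian IBD fractions for full sibs", {
  sim <- simulate_family_study(n_pedigrees = 30, generations = 2, sibship = 2,
                               n_variants = 8000, fst = c(0.01, 0.01),
                               alpha = c(1, 1), linkage = FALSE, seed = 12)
  Phi <- pedigree_kinship(sim$ped)
  ids <- rownames(sim$genotypes$dosage)
  ap <- all_pairs(length(ids))
  sib <- ap[Phi[ids, ids][ap] == 0.25 &
            apply(ap, 1, function(r) {
              i <- ids[r[1]]; j <- ids[r[2]]
              fi <- sim$ped$father[sim$ped$id == i]
              fj <- sim$ped$father[sim$ped$id == j]
              !is.na(fi) && !is.na(fj) && fi == fj
            }), , drop = FALSE]
  fit <- mle_ibd_em(sim$genotypes, pairs = sib)
  expect_lt(abs(mean(fit$k0) - 0.25), 0.03)
  expect_lt(abs(mean(fit$k1) - 0.50), 0.03)
  expect_lt(abs(mean(fit$k2) - 0.25), 0.03)
})

test_that("relationship classification rounds to the nearest expected kinship", {
  expect_equal(classify_relationship(0.23), "1st")
  expect_equal(classify_relationship(0.19), "1st")    # 0.06 < 0.065
  expect_equal(classify_relationship(0.01), "unrelated")
  # exact midpoints go to the more distant degree
  expect_equal(classify_relationship(0.1875), "2nd")
  expect_equal(classify_relationship(0.015625), "unrelated")
  expect_equal(classify_relationship(c(0.5, 0.125, 0)), c("1st", "2nd", "unrelated"))
})

test_that("classification rates match a brute-force confusion tally", {
  withr::with_seed(13, {
    truth <- sample(c("1st", "2nd", "3rd", "4th", "unrelated"), 500, TRUE)
    called <- truth
    flip <- runif(500) < 0.3
    called[flip] <- sample(c("1st", "2nd", "3rd", "4th", "unrelated"),
                           sum(flip), TRUE)
  })
  tab <- classification_table(truth, called)
  for (d in tab$degree) {
    expect_equal(tab$rate[tab$degree == d],
                 sum(truth == d & called == d) / sum(truth == d))
  }
  expect_equal(classification_table(rep("1st", 3), rep("1st", 3))$rate[1], 1)
  expect_true(is.na(classification_table("1st", "1st")$rate[5]))  # empty cell
})

test_that("chromosome aggregation weights by marker count then clamps", {
  base <- data.frame(i = 1L, j = 2L, id1 = "a", id2 = "b",
                     kinship = 0.2, n_markers = 100, estimator = "mom")
  c2 <- base; c2$kinship <- 0.3; c2$n_markers <- 300
  agg <- aggregate_chromosomes(list(base, c2))
  expect_equal(agg$kinship, 0.275)
  expect_equal(agg$n_markers, 400)
  expect_equal(aggregate_chromosomes(list(base))$kinship, 0.2)   # identity
  neg <- base; neg$kinship <- -0.05
  expect_equal(aggregate_chromosomes(list(neg))$kinship, 0)      # clamping
})

test_that("greedy unrelated-set partition follows the stated rule", {
  # trio: the child (2 super-threshold pairs) is removed, parents kept
  Phi <- pedigree_kinship(trio_ped())
  part <- pcair_partition(Phi)
  expect_setequal(part$unrelated, c("F", "M"))
  expect_equal(part$related, "C")
  # all kinship below threshold: everyone unrelated
  K <- diag(0.5, 4); rownames(K) <- colnames(K) <- letters[1:4]
  expect_equal(length(pcair_partition(K)$related), 0)
  # duplicate pair: exactly one of the two removed
  K2 <- K; K2["a", "b"] <- K2["b", "a"] <- 0.5
  part2 <- pcair_partition(K2)
  expect_equal(length(part2$related), 1)
  expect_true(part2$related %in% c("a", "b"))
  expect_error(pcair_partition(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("PC-Relate reduces to the classical form in homogeneous samples", {
  sim <- simulate_family_study(n_pedigrees = 30, generations = 2, sibship = 1,
                               n_variants = 1500, fst = c(0.01, 0.01),
                               alpha = c(1, 1), linkage = FALSE, seed = 14)
  g <- sim$genotypes
  ids <- rownames(g$dosage)
  # 0 PCs (intercept only): mu is the unrelated-set frequency; compare with
  # the direct classical ratio estimator computed from those frequencies
  founders <- sim$ped$id[is_founder(sim$ped)]
  pcs <- matrix(numeric(0), length(ids), 0, dimnames = list(ids, NULL))
  kin <- pcrelate(g, pcs, unrelated = founders, n_pcs = 0)
  p <- colMeans(g$dosage[founders, ], na.rm = TRUE) / 2
  eps <- 1 / (2 * length(ids))
  p <- pmin(pmax(p, eps), 1 - eps)
  R <- sweep(g$dosage, 2, 2 * p)
  den <- 4 * sum(p * (1 - p))
  direct <- tcrossprod(R) / den
  expect_equal(kin$kinship, direct[cbind(kin$i, kin$j)], tolerance = 1e-10)
})

test_that("PC-Relate removes structure bias that classical kinship keeps", {
  # two diverged populations, unrelated individuals only
  withr::with_seed(15, {
    q <- rbind(matrix(c(1, 0), 60, 2, byrow = TRUE),
               matrix(c(0, 1), 60, 2, byrow = TRUE))
    fr <- simulate_frequencies(3000, c("A", "B"), fst = c(0.1, 0.1),
                               maf_spectrum = maf_uniform(0.1, 0.5), seed = 16)
    g <- sim_unrelated(q, fr$freq, seed = 17)
  })
  grm <- grm_ratio_of_sums(g)
  cross <- outer(1:120, 1:120, function(i, j) (i <= 60) != (j <= 60))
  classical_phi <- grm$psi / 2
  pcs <- pca_grm(grm, n_components = 2)$scores
  kin <- pcrelate(g, pcs, unrelated = rownames(g$dosage), n_pcs = 2)
  M <- matrix(NA_real_, 120, 120)
  M[cbind(kin$i, kin$j)] <- kin$kinship
  pcr_cross <- mean(M[cross], na.rm = TRUE)
  cls_cross <- mean(classical_phi[upper.tri(classical_phi) & cross])
  expect_lt(abs(pcr_cross), 0.01)
  expect_gt(abs(cls_cross), 3 * abs(pcr_cross) + 0.01)

  # admixed parent-offspring recovery
  sim <- simulate_family_study(n_pedigrees = 30, generations = 2, sibship = 1,
                               n_variants = 4000, fst = c(0.2, 0.2),
                               alpha = c(2, 1), linkage = FALSE, seed = 18)
  Phi <- pedigree_kinship(sim$ped)
  ids <- rownames(sim$genotypes$dosage)
  part <- pcair_partition(Phi[ids, ids])
  sc <- pcair_scores(sim$genotypes, part$unrelated, n_pcs = 2)
  kin2 <- pcrelate(sim$genotypes, sc$scores, part$unrelated, n_pcs = 2)
  truth <- Phi[ids, ids][cbind(kin2$i, kin2$j)]
  expect_lt(abs(mean(kin2$kinship[truth == 0.25]) - 0.25), 0.015)
})

test_that("all estimators agree on duplicate pairs given common markers", {
  withr::with_seed(19, {
    p <- runif(6000, 0.2, 0.5)
    x <- rbinom(6000, 2, p)
    others <- matrix(rbinom(6000 * 100, 2, rep(p, each = 100)), 100, 6000)
    g <- toy_geno(unname(rbind(x, x, others)))
  })
  pr <- cbind(1L, 2L)
  ids <- rownames(g$dosage)
  expect_lt(abs(king_robust(g, pr)$kinship - 0.5), 0.02)
  expect_lt(abs(mom_ibd(g, pairs = pr)$kinship - 0.5), 0.02)
  expect_lt(abs(mle_ibd_em(g, pairs = pr)$kinship - 0.5), 0.02)
  pcs <- pca_grm(grm_ratio_of_sums(g), 2)$scores
  expect_lt(abs(pcrelate(g, pcs, unrelated = ids[-(1:2)], n_pcs = 0,
                         pairs = pr)$kinship - 0.5), 0.02)
})
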