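test_that("Balding-Nichols frequencies have the right moments and limits", {
  # zero-differentiation limit: population frequencies collapse onto the
  # ancestral frequency
  fr0 <- simulate_frequencies(200, c("A", "B"), fst = c(1e-6, 1e-6),
                              maf_spectrum = maf_uniform(0.1, 0.5), seed = 11)
  expect_lt(max(abs(sweep(fr0$freq, 2, fr0$ancestral_freq))), 1e-2)

  # moment check at Fst = 0.1 against the Beta parameterization
  fr <- simulate_frequencies(50000, c("A", "B"), fst = c(0.1, 0.1),
                             maf_spectrum = maf_uniform(0.2, 0.4), seed = 12)
  dev <- fr$freq[1, ] - fr$ancestral_freq
  expect_lt(abs(mean(dev)), 0.002)
  ratio <- var(dev) / mean(0.1 * fr$ancestral_freq * (1 - fr$ancestral_freq))
  expect_lt(abs(ratio - 1), 0.05)

  # determinism and input validation
  expect_identical(simulate_frequencies(50, "A", 0.1, maf_uniform(), seed = 3),
                   simulate_frequencies(50, "A", 0.1, maf_uniform(), seed = 3))
  expect_error(simulate_frequencies(10, "A", fst = 0), "fst")
  expect_error(simulate_frequencies(10, "A", fst = 0.1,
                                    maf_spectrum = list()), "spectrum")
})

test_that("wgs-like spectrum places the configured mass on rare variants", {
  fr <- simulate_frequencies(20000, "A", 0.1, maf_wgs(rare_prop = 0.6), seed = 5)
  expect_lt(abs(mean(fr$ancestral_freq < 0.01) - 0.6), 0.02)
})

test_that("simulated pedigrees have the forced structure and degree census", {
  # trios: exactly 2 parent-offspring pairs and 1 mate pair each
  ped <- simulate_pedigrees(3, generations = 2, sibship = 1, seed = 1)
  expect_equal(nrow(ped), 9)
  Phi <- pedigree_kinship(ped)
  for (f in unique(ped$family)) {
    ids <- ped$id[ped$family == f]
    sub <- Phi[ids, ids]
    expect_equal(sum(sub[upper.tri(sub)] == 0.25), 2)  # two PO pairs
    expect_equal(sum(sub[upper.tri(sub)] == 0), 1)     # the mate pair
  }

  # 20 pedigrees -> 20 connected components (distinct family labels,
  # no cross-family parent links)
  ped20 <- simulate_pedigrees(20, 3, 2, seed = 2)
  expect_equal(length(unique(ped20$family)), 20)
  fam_of <- setNames(ped20$family, ped20$id)
  ok <- is.na(ped20$father) | fam_of[ped20$father] == ped20$family
  expect_true(all(ok))

  # degree census vs brute-force pair enumeration through the kinship graph
  ped1 <- simulate_pedigrees(1, generations = 4, sibship = 2, seed = 3)
  Phi1 <- pedigree_kinship(ped1)
  pairs <- t(combn(nrow(ped1), 2))
  census <- table(true_degree(Phi1[pairs]), useNA = "no")
  # brute force: count via explicit relationship walks
  kids_of <- function(id) ped1$id[!is.na(ped1$father) &
                                  (ped1$father == id | ped1$mother == id)]
  po <- sum(vapply(ped1$id, function(i) length(kids_of(i)), numeric(1)))
  sibs <- 0
  for (i in seq_len(nrow(ped1))) for (j in seq_len(nrow(ped1))) if (i < j) {
    if (!is.na(ped1$father[i]) && !is.na(ped1$father[j]) &&
        ped1$father[i] == ped1$father[j] && ped1$mother[i] == ped1$mother[j])
      sibs <- sibs + 1
  }
  expect_equal(unname(census["1st"]), po + sibs)
  expect_true(all(c("1st", "2nd", "3rd", "4th") %in% names(census)))

  expect_error(simulate_pedigrees(0), "n_pedigrees")
  expect_error(simulate_pedigrees(1, generations = 1), "generations")
})

test_that("founder haplotypes follow the Dirichlet/Poisson tract model", {
  fr <- simulate_frequencies(300, c("A", "B", "C"), fst = rep(0.1, 3),
                             maf_spectrum = maf_uniform(0.1, 0.5), seed = 1)
  map <- simulate_variant_map(300, length_cM = 100, seed = 2)
  ped <- simulate_pedigrees(40, generations = 2, sibship = 1, seed = 3)

  # degenerate Dirichlet: all tracts from the dominant population
  adx <- admixture_config(c(1e6, 1e-6, 1e-6))
  hp <- simulate_founder_haplotypes(ped, fr, adx, map, seed = 4)
  expect_true(all(hp$anc1 == 1L) && all(hp$anc2 == 1L))

  # Poisson breakpoint intensity: 8 per Morgan on a 1-Morgan chromosome
  adx8 <- admixture_config(c(1, 1, 1), generations_since_admixture = 8)
  hp8 <- simulate_founder_haplotypes(ped, fr, adx8, map, seed = 5)
  nb <- vapply(hp8$tracts, function(tr) {
    nrow(tr$h1) + nrow(tr$h2) - 2   # raw breakpoints (founder tracts unmerged)
  }, numeric(1))
  n_haps <- 2 * length(hp8$tracts)
  expect_lt(abs(mean(nb) / 2 - 8), 3 * sqrt(8 / n_haps))

  # Dirichlet mean of realized global ancestry over many founders
  founders_only <- hp8$q
  expect_lt(max(abs(colMeans(founders_only) - 1 / 3)), 0.06)

  expect_error(simulate_founder_haplotypes(ped, fr, adx8,
    simulate_variant_map(299, seed = 1)), "mismatch")
})

test_that("gene dropping is Mendelian-consistent with Poisson crossovers", {
  fr <- simulate_frequencies(400, c("A", "B"), fst = c(0.2, 0.2),
                             maf_spectrum = maf_uniform(0.1, 0.5), seed = 1)
  map <- simulate_variant_map(400, length_cM = 200, seed = 2)  # 2 Morgans
  ped <- simulate_pedigrees(25, generations = 3, sibship = 2, seed = 3)
  adx <- admixture_config(c(2, 2), generations_since_admixture = 5)
  hp <- simulate_founder_haplotypes(ped, fr, adx, map, seed = 4)
  dr <- drop_genes(ped, hp, seed = 5)
  dos <- dr$genotypes$dosage

  # zero Mendelian inconsistencies at every variant
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in which(!is.na(ped$father))) {
    ci <- dos[ped$id[i], ]; fi <- dos[ped$father[i], ]; mi <- dos[ped$mother[i], ]
    expect_true(all(ci >= (fi == 2) + (mi == 2)))
    expect_true(all(ci <= 2 - (fi == 0) - (mi == 0)))
  }

  # child global ancestry = average of its two transmitted haplotypes,
  # exactly, per realization (length-based bookkeeping identity)
  props <- global_ancestry_from_local(dr$ancestry)
  i <- which(!is.na(ped$father))[1]
  tr <- dr$ancestry$tracts[[idx[ped$id[i]]]]
  hap_prop <- function(trh, k) sum((trh$end_cM - trh$start_cM)[trh$pop == k]) / 200
  expect_equal(props[ped$id[i], 1],
               (hap_prop(tr$h1, 1) + hap_prop(tr$h2, 1)) / 2, tolerance = 1e-12)
  expect_equal(unname(rowSums(props)), rep(1, nrow(props)))

})

test_that("meioses draw ~L/100 crossovers on an L-cM chromosome", {
  # parents whose haplotype 1 is entirely population 1 and haplotype 2
  # entirely population 2: every crossover creates a label switch in the
  # transmitted haplotype, so child tract count - 1 counts crossovers
  n_kids <- 150
  ped <- pedigree(id = c("F", "M", paste0("K", 1:n_kids)),
                  family = "X",
                  father = c(NA, NA, rep("F", n_kids)),
                  mother = c(NA, NA, rep("M", n_kids)),
                  sex = c(1, 2, rep(1, n_kids)))
  S <- 50; L <- 200
  v <- data.frame(id = paste0("v", 1:S), chrom = "1", bp = (1:S) * 4e6,
                  cM = (1:S) * 4, ref = "A", alt = "G")
  map <- list(variants = v, length_cM = L, chrom = "1")
  one <- data.frame(start_cM = 0, end_cM = L, pop = 1)
  two <- data.frame(start_cM = 0, end_cM = L, pop = 2)
  founders <- structure(list(
    samples = c("F", "M"),
    h1 = matrix(1L, 2, S, dimnames = list(c("F", "M"), v$id)),
    h2 = matrix(0L, 2, S, dimnames = list(c("F", "M"), v$id)),
    anc1 = matrix(1L, 2, S), anc2 = matrix(2L, 2, S),
    q = matrix(0.5, 2, 2), tracts = list(F = list(h1 = one, h2 = two),
                                         M = list(h1 = one, h2 = two)),
    map = map, linkage = TRUE, pop_labels = c("P1", "P2")),
    class = "haplotype_set")
  dr <- drop_genes(ped, founders, seed = 99)
  xo <- vapply(3:(n_kids + 2), function(i)
    nrow(dr$ancestry$tracts[[i]]$h1) - 1, numeric(1))
  expect_lt(abs(mean(xo) - L / 100), 3 * sqrt(L / 100 / n_kids))
})

test_that("unlinked gene dropping reproduces expected founder dosages", {
  # E[dosage | q] = 2 sum_k q_k freq_k, testable by regression over founders
  fr <- simulate_frequencies(2000, c("A", "B"), fst = c(0.15, 0.15),
                             maf_spectrum = maf_uniform(0.1, 0.5), seed = 21)
  map <- simulate_variant_map(2000, seed = 22)
  ped <- simulate_pedigrees(100, generations = 2, sibship = 1, seed = 23)
  adx <- admixture_config(c(2, 1))
  hp <- simulate_founder_haplotypes(ped, fr, adx, map, linkage = FALSE, seed = 24)
  expected <- 2 * hp$q %*% fr$freq
  observed <- hp$h1 + hp$h2
  fitl <- lm(as.vector(observed) ~ as.vector(expected))
  expect_equal(unname(coef(fitl)), c(0, 1), tolerance = 0.02)
})

test_that("phenotype simulation matches its generating moments", {
  sim <- simulate_family_study(n_pedigrees = 30, generations = 2, sibship = 2,
                               n_variants = 50, linkage = FALSE, seed = 31)
  # pure-noise model: trait variance tracks sigma_e2_curve(age)
  cfg0 <- phenotype_config(sigma_g2 = 0, sigma_e2_curve = function(a) 25,
                           covariate_effects = c(med = 0, smoke = 0, sex = 0),
                           n_visits = 3, visit_increment = 5)
  ph <- simulate_phenotypes(sim$genotypes, sim$ancestry, sim$ped, cfg0, seed = 32)
  expect_lt(abs(var(ph$trait) / 25 - 1), 0.15)

  # ages strictly increase by the visit increment
  byid <- split(ph$age, ph$sample)
  expect_true(all(vapply(byid, function(a) all(diff(sort(a)) == 5), logical(1))))

  # determinism and validation
  ph2 <- simulate_phenotypes(sim$genotypes, sim$ancestry, sim$ped, cfg0, seed = 32)
  expect_identical(ph, ph2)
  expect_error(simulate_phenotypes(sim$genotypes, sim$ancestry, sim$ped,
    phenotype_config(sigma_e2_curve = function(a) -1), seed = 1), "positive")
})
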