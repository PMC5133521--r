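#' Minor-allele-frequency spectrum specifications
#'
#' `maf_uniform()` draws ancestral frequencies uniformly on `[lo, hi]`.
#' `maf_wgs()` is a two-component mixture emulating a sequencing panel
#' dominated by rare variation: a fraction `rare_prop` of variants has
#' ancestral MAF drawn uniformly from `rare_range`, the rest from
#' `common_range`. The default rare mass of 60 % mirrors panels where most
#' discovered variants have founder MAF of 1 % or less.
#'
#' @param lo,hi bounds of the uniform spectrum, inside (0, 0.5].
#' @param rare_prop fraction of rare variants.
#' @param rare_range,common_range MAF ranges of the two components.
#' @return a spectrum specification list
#' @export
maf_uniform <- function(lo = 0.05, hi = 0.5) {
  stopifnot(lo > 0, hi <= 0.5, lo < hi)
  list(type = "uniform", lo = lo, hi = hi)
}

#' @rdname maf_uniform
#' @export
maf_wgs <- function(rare_prop = 0.6, rare_range = c(5e-4, 0.01),
                    common_range = c(0.01, 0.5)) {
  stopifnot(rare_prop >= 0, rare_prop <= 1)
  list(type = "wgs", rare_prop = rare_prop, rare_range = rare_range,
       common_range = common_range)
}

draw_spectrum <- function(spec, n) {
  if (is.null(spec$type)) stop("empty or invalid MAF spectrum specification")
  switch(spec$type,
    uniform = runif(n, spec$lo, spec$hi),
    wgs = {
      rare <- runif(n) < spec$rare_prop
      p <- numeric(n)
      p[rare] <- runif(sum(rare), spec$rare_range[1], spec$rare_range[2])
      p[!rare] <- runif(sum(!rare), spec$common_range[1], spec$common_range[2])
      p
    },
    stop("unknown MAF spectrum type: ", spec$type))
}

#' Simulate ancestry-differentiated allele frequencies
#'
#' Draws an ancestral frequency per variant from the requested spectrum and,
#' for each population, an alternate-allele frequency from the
#' Balding-Nichols parameterization: a Beta with mean equal to the ancestral
#' frequency p and variance `fst * p * (1 - p)`.
#'
#' @param n_variants number of variants (>= 1).
#' @param pop_labels population names, e.g. `c("AFR","AMR","ASN","EUR")`.
#' @param fst per-population differentiation, each strictly in (0, 1).
#' @param maf_spectrum see [maf_uniform()] / [maf_wgs()].
#' @param seed integer seed; identical seeds give identical output.
#' @return object of class `pop_freqs` with fields `n_pops`, `pop_labels`,
#'   `freq` (pops x variants), `ancestral_freq`, `fst`.
#' @export
simulate_frequencies <- function(n_variants, pop_labels, fst,
                                 maf_spectrum = maf_wgs(), seed = NULL) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (length(fst) != length(pop_labels)) stop("fst must match pop_labels in length")
  if (any(fst <= 0 | fst >= 1)) stop("each fst must lie strictly in (0, 1)")
  with_seed(seed, {
    p <- draw_spectrum(maf_spectrum, n_variants)
    freq <- matrix(NA_real_, length(pop_labels), n_variants,
                   dimnames = list(pop_labels, NULL))
    for (k in seq_along(pop_labels)) {
      a <- p * (1 - fst[k]) / fst[k]
      b <- (1 - p) * (1 - fst[k]) / fst[k]
      freq[k, ] <- rbeta(n_variants, a, b)
    }
    structure(list(n_pops = length(pop_labels), pop_labels = pop_labels,
                   freq = freq, ancestral_freq = p, fst = fst),
              class = "pop_freqs")
  })
}

#' Admixture configuration
#'
#' @param dirichlet_alpha positive Dirichlet concentration per population;
#'   founder admixture proportions are drawn from this distribution.
#' @param generations_since_admixture positive; Poisson intensity (per
#'   Morgan) of ancestry-tract breakpoints along founder haplotypes.
#' @return list of class `admixture_config`
#' @export
admixture_config <- function(dirichlet_alpha, generations_since_admixture = 8) {
  if (any(dirichlet_alpha <= 0)) stop("all dirichlet_alpha must be > 0")
  if (generations_since_admixture <= 0) stop("generations_since_admixture must be > 0")
  structure(list(dirichlet_alpha = dirichlet_alpha,
                 generations_since_admixture = generations_since_admixture),
            class = "admixture_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate multi-generation pedigrees
#'
#' Builds `n_pedigrees` families, each founded by one couple. Every couple
#' has `sibship` children; in all generations but the last, each child
#' marries a newly introduced founder and the couple reproduces, so the
#' family spans `generations` generations. All non-founders have both
#' parents in the table; cousin marriages never occur.
#'
#' @param n_pedigrees number of families (>= 1).
#' @param generations generations per family (>= 2).
#' @param sibship children per couple (>= 1).
#' @param seed integer seed (controls child sexes).
#' @return a [pedigree()] with `n_pedigrees` connected components.
#' @export
simulate_pedigrees <- function(n_pedigrees, generations = 3, sibship = 3,
                               seed = NULL) {
  if (n_pedigrees < 1) stop("n_pedigrees must be >= 1")
  if (generations < 2) stop("generations must be >= 2")
  if (sibship < 1) stop("sibship sizes must be >= 1")
  with_seed(seed, {
    rows <- list()
    for (f in seq_len(n_pedigrees)) {
      fam <- sprintf("F%02d", f)
      nid <- 0L
      new_id <- function() { nid <<- nid + 1L; sprintf("%s_I%03d", fam, nid) }
      dad <- new_id(); mom <- new_id()
      rows[[length(rows) + 1L]] <- data.frame(id = c(dad, mom), family = fam,
        father = NA_character_, mother = NA_character_, sex = c(1L, 2L))
      couples <- list(c(dad, mom))
      for (g in 2:generations) {
        next_couples <- list()
        for (cp in couples) {
          for (s in seq_len(sibship)) {
            child <- new_id()
            csex <- sample(1:2, 1)
            rows[[length(rows) + 1L]] <- data.frame(id = child, family = fam,
              father = cp[1], mother = cp[2], sex = csex)
            if (g < generations) {
              spouse <- new_id()
              rows[[length(rows) + 1L]] <- data.frame(id = spouse, family = fam,
                father = NA_character_, mother = NA_character_,
                sex = if (csex == 1L) 2L else 1L)
              next_couples[[length(next_couples) + 1L]] <-
                if (csex == 1L) c(child, spouse) else c(spouse, child)
            }
          }
        }
        couples <- next_couples
      }
    }
    tab <- do.call(rbind, rows)
    pedigree(tab$id, tab$family, tab$father, tab$mother, tab$sex)
  })
}

#' Simulate variant positions on a linear genetic map
#'
#' Places `n_variants` at sorted uniform bp positions on one chromosome with
#' a constant recombination rate (`bp_per_cM` base pairs per centimorgan).
#'
#' @param n_variants number of variants.
#' @param length_cM chromosome map length in cM.
#' @param chrom chromosome label.
#' @param bp_per_cM physical-to-map scale (default 1 Mb/cM).
#' @param seed integer seed.
#' @return list with `variants` (id, chrom, bp, cM, ref, alt) and `length_cM`.
#' @export
simulate_variant_map <- function(n_variants, length_cM = 100, chrom = "1",
                                 bp_per_cM = 1e6, seed = NULL) {
  with_seed(seed, {
    bp <- sort(sample.int(round(length_cM * bp_per_cM), n_variants))
    data.frame(id = sprintf("%s:%d", chrom, bp), chrom = chrom, bp = bp,
               cM = bp / bp_per_cM, ref = "A", alt = "G",
               stringsAsFactors = FALSE) -> v
    list(variants = v, length_cM = length_cM, chrom = chrom)
  })
}

# draw one founder haplotype: tract breakpoints from a Poisson process of
# rate G per Morgan, labels iid from q; returns list(tracts, pop_at_variant)
draw_founder_haplotype <- function(q, G, length_cM, v_cM) {
  n_break <- rpois(1, G * length_cM / 100)
  breaks <- sort(runif(n_break, 0, length_cM))
  starts <- c(0, breaks); ends <- c(breaks, length_cM)
  pop <- sample.int(length(q), length(starts), replace = TRUE, prob = q)
  tr <- data.frame(start_cM = starts, end_cM = ends, pop = pop)
  idx <- findInterval(v_cM, starts, rightmost.closed = FALSE)
  list(tracts = tr, pop_at_variant = pop[idx])
}

#' Simulate founder haplotypes with known local ancestry
#'
#' Each founder receives admixture proportions `q ~ Dirichlet(alpha)`. With
#' `linkage = TRUE` each haplotype is a mosaic of ancestry tracts whose
#' breakpoints follow a Poisson process of intensity
#' `generations_since_admixture` per Morgan and whose labels are drawn
#' independently from `q`; with `linkage = FALSE` every variant's ancestry
#' label is drawn independently from `q` (unlinked-marker mode). Alleles are
#' Bernoulli draws from the tract population's frequency.
#'
#' @param ped a [pedigree()].
#' @param freqs a `pop_freqs` object from [simulate_frequencies()].
#' @param admix an [admixture_config()].
#' @param map a variant map from [simulate_variant_map()].
#' @param linkage simulate ancestry tracts (`TRUE`, default) or fully
#'   independent markers (`FALSE`).
#' @param seed integer seed.
#' @return object of class `haplotype_set`: allele matrices `h1`, `h2`
#'   (founders x variants), ancestry label matrices `anc1`, `anc2`, founder
#'   admixture proportions `q`, tract lists, and the map.
#' @export
simulate_founder_haplotypes <- function(ped, freqs, admix, map,
                                        linkage = TRUE, seed = NULL) {
  v <- map$variants
  if (ncol(freqs$freq) != nrow(v)) stop("map/variant dimension mismatch with frequencies")
  if (is.unsorted(v$cM, strictly = FALSE)) stop("map positions must be non-decreasing")
  fid <- ped$id[is_founder(ped)]
  nf <- length(fid); S <- nrow(v); K <- freqs$n_pops
  with_seed(seed, {
    q <- matrix(NA_real_, nf, K, dimnames = list(fid, freqs$pop_labels))
    h1 <- h2 <- matrix(NA_integer_, nf, S, dimnames = list(fid, v$id))
    a1 <- a2 <- matrix(NA_integer_, nf, S, dimnames = list(fid, v$id))
    tracts <- if (linkage) setNames(vector("list", nf), fid) else NULL
    for (i in seq_len(nf)) {
      qi <- rdirichlet1(admix$dirichlet_alpha)
      q[i, ] <- qi
      for (h in 1:2) {
        if (linkage) {
          hp <- draw_founder_haplotype(qi, admix$generations_since_admixture,
                                       map$length_cM, v$cM)
          pops <- hp$pop_at_variant
          if (h == 1) tracts[[i]] <- list(h1 = hp$tracts) else
            tracts[[i]]$h2 <- hp$tracts
        } else {
          pops <- sample.int(K, S, replace = TRUE, prob = qi)
        }
        al <- rbinom(S, 1L, freqs$freq[cbind(pops, seq_len(S))])
        if (h == 1) { h1[i, ] <- al; a1[i, ] <- pops }
        else        { h2[i, ] <- al; a2[i, ] <- pops }
      }
    }
    structure(list(samples = fid, h1 = h1, h2 = h2, anc1 = a1, anc2 = a2,
                   q = q, tracts = tracts, map = map, linkage = linkage,
                   pop_labels = freqs$pop_labels),
              class = "haplotype_set")
  })
}

# one meiosis under the Haldane model (Poisson crossovers, no interference):
# returns the transmitted allele vector, ancestry labels, and (if parent
# tracts are given) the child tract data frame
meiosis_linked <- function(al1, al2, an1, an2, tr1, tr2, v_cM, length_cM) {
  k <- rpois(1, length_cM / 100)
  cross <- sort(runif(k, 0, length_cM))
  start <- sample(1:2, 1)
  seg_start <- c(0, cross); seg_end <- c(cross, length_cM)
  seg_hap <- ((start - 1L + seq_along(seg_start) - 1L) %% 2L) + 1L
  idx <- findInterval(v_cM, seg_start)
  from1 <- seg_hap[idx] == 1L
  allele <- ifelse(from1, al1, al2)
  anc <- ifelse(from1, an1, an2)
  tr <- NULL
  if (!is.null(tr1)) {
    pieces <- list()
    for (s in seq_along(seg_start)) {
      src <- if (seg_hap[s] == 1L) tr1 else tr2
      sel <- src[src$end_cM > seg_start[s] & src$start_cM < seg_end[s], , drop = FALSE]
      if (nrow(sel)) {
        sel$start_cM <- pmax(sel$start_cM, seg_start[s])
        sel$end_cM <- pmin(sel$end_cM, seg_end[s])
        pieces[[length(pieces) + 1L]] <- sel
      }
    }
    tr <- do.call(rbind, pieces)
    # merge adjacent tracts with equal labels
    if (nrow(tr) > 1) {
      keep <- c(TRUE, tr$pop[-1] != tr$pop[-nrow(tr)])
      grp <- cumsum(keep)
      tr <- data.frame(start_cM = tapply(tr$start_cM, grp, min),
                       end_cM = tapply(tr$end_cM, grp, max),
                       pop = tr$pop[keep])
    }
    rownames(tr) <- NULL
  }
  list(allele = as.integer(allele), anc = as.integer(anc), tracts = tr)
}

#' Drop genes through a pedigree
#'
#' Transmits founder haplotypes to descendants. With `linkage = TRUE`
#' (matching the founder set) each meiosis recombines the parental
#' haplotypes with crossovers from a Poisson process per Morgan (Haldane
#' model, no interference); ancestry labels travel with the alleles. With
#' `linkage = FALSE` every marker segregates independently. Genotypes are
#' the sum of the two transmitted alleles.
#'
#' @param ped a [pedigree()].
#' @param founders a `haplotype_set` from [simulate_founder_haplotypes()].
#' @param seed integer seed.
#' @return list with `genotypes` (a [genotype_matrix()]), `ancestry`
#'   (a [local_ancestry()]), and `haplotypes` (allele matrices for all
#'   samples, for phased output).
#' @export
drop_genes <- function(ped, founders, seed = NULL) {
  ord <- attr(ped, "order") %||% pedigree_order(ped)
  v <- founders$map$variants; S <- nrow(v)
  ids <- ped$id
  n <- length(ids)
  with_seed(seed, {
    h1 <- h2 <- a1 <- a2 <- matrix(NA_integer_, n, S, dimnames = list(ids, v$id))
    tracts <- if (founders$linkage) setNames(vector("list", n), ids) else NULL
    fmatch <- match(founders$samples, ids)
    h1[fmatch, ] <- founders$h1; h2[fmatch, ] <- founders$h2
    a1[fmatch, ] <- founders$anc1; a2[fmatch, ] <- founders$anc2
    if (founders$linkage) tracts[fmatch] <- founders$tracts
    idx <- setNames(seq_len(n), ids)
    for (i in ord) {
      if (is.na(ped$father[i])) next
      fa <- idx[[ped$father[i]]]; mo <- idx[[ped$mother[i]]]
      if (anyNA(h1[fa, 1]) || anyNA(h1[mo, 1]))
        stop("parents must be processed before children (cyclic pedigree?)")
      for (par in c(fa, mo)) {
        if (founders$linkage) {
          tp <- tracts[[par]]
          mei <- meiosis_linked(h1[par, ], h2[par, ], a1[par, ], a2[par, ],
                                tp$h1, tp$h2, v$cM, founders$map$length_cM)
          if (par == fa) {
            h1[i, ] <- mei$allele; a1[i, ] <- mei$anc; tracts[[i]] <- list(h1 = mei$tracts)
          } else {
            h2[i, ] <- mei$allele; a2[i, ] <- mei$anc; tracts[[i]]$h2 <- mei$tracts
          }
        } else {
          pick <- runif(S) < 0.5
          al <- ifelse(pick, h1[par, ], h2[par, ])
          an <- ifelse(pick, a1[par, ], a2[par, ])
          if (par == fa) { h1[i, ] <- al; a1[i, ] <- an }
          else           { h2[i, ] <- al; a2[i, ] <- an }
        }
      }
    }
    dos <- h1 + h2
    storage.mode(dos) <- "integer"
    g <- genotype_matrix(dos, v)
    la <- local_ancestry(a1, a2, founders$pop_labels, v$cM,
                         founders$map$length_cM, tracts = tracts,
                         chrom = founders$map$chrom)
    list(genotypes = g, ancestry = la, haplotypes = list(h1 = h1, h2 = h2))
  })
}

#' Phenotype-model configuration for the simulator
#'
#' Defines the generating model for a longitudinal, blood-pressure-like
#' trait: per visit the trait is an intercept plus covariate effects
#' (medication, smoking, sex), allelic effects at designated causal
#' variants, local-ancestry effects at designated loci, a subject-level
#' polygenic deviation with covariance `2 * Phi * sigma_g2` (Phi = pedigree
#' kinship), and independent noise with age-dependent variance
#' `sigma_e2_curve(age)`.
#'
#' @param intercept trait mean at the reference level.
#' @param causal `NULL` or data frame (`variant_id`, `beta`).
#' @param ancestry_loci `NULL` or data frame (`variant_id`, `population`,
#'   `beta`) of local-ancestry dosage effects.
#' @param sigma_g2 polygenic additive variance (>= 0).
#' @param sigma_e2_curve function of age returning the environmental
#'   variance; must be positive over the simulated age range.
#' @param covariate_effects named vector with `med`, `smoke`, `sex`.
#' @param med_rate,smoke_rate Bernoulli rates of medication use and smoking.
#' @param n_visits,age_range,visit_increment visit schedule: baseline ages
#'   uniform on `age_range`, advancing `visit_increment` years per visit.
#' @return list of class `phenotype_config`
#' @export
phenotype_config <- function(intercept = 120, causal = NULL, ancestry_loci = NULL,
                             sigma_g2 = 20, sigma_e2_curve = function(age) 40 + 0.5 * age,
                             covariate_effects = c(med = -5, smoke = 3, sex = -2),
                             med_rate = 0.3, smoke_rate = 0.2,
                             n_visits = 3, age_range = c(20, 60),
                             visit_increment = 5) {
  if (sigma_g2 < 0) stop("sigma_g2 must be >= 0")
  structure(list(intercept = intercept, causal = causal,
                 ancestry_loci = ancestry_loci, sigma_g2 = sigma_g2,
                 sigma_e2_curve = sigma_e2_curve,
                 covariate_effects = covariate_effects, med_rate = med_rate,
                 smoke_rate = smoke_rate, n_visits = n_visits,
                 age_range = age_range, visit_increment = visit_increment),
            class = "phenotype_config")
}

#' Simulate longitudinal phenotypes on a pedigree
#'
#' @param geno a [genotype_matrix()] (for causal-variant dosages).
#' @param ancestry a [local_ancestry()] (for ancestry-effect loci); may be
#'   `NULL` when `cfg$ancestry_loci` is `NULL`.
#' @param ped the [pedigree()].
#' @param cfg a [phenotype_config()].
#' @param seed integer seed.
#' @return long-format data frame (`sample`, `visit`, `age`, `trait`,
#'   `med`, `smoke`, `sex`), one row per subject-visit.
#' @export
simulate_phenotypes <- function(geno, ancestry, ped, cfg, seed = NULL) {
  ids <- rownames(geno$dosage)
  n <- length(ids)
  with_seed(seed, {
    ages0 <- runif(n, cfg$age_range[1], cfg$age_range[2])
    all_ages <- rep(ages0, cfg$n_visits) +
      rep((seq_len(cfg$n_visits) - 1) * cfg$visit_increment, each = n)
    ve <- cfg$sigma_e2_curve(all_ages)
    if (any(!is.finite(ve)) || any(ve <= 0))
      stop("sigma_e2_curve must be positive over the simulated age range")
    med <- rbinom(n, 1, cfg$med_rate)
    smoke <- rbinom(n, 1, cfg$smoke_rate)
    sex <- ped$sex[match(ids, ped$id)] - 1L  # 0 = male, 1 = female
    fixed <- cfg$intercept + cfg$covariate_effects["med"] * med +
      cfg$covariate_effects["smoke"] * smoke + cfg$covariate_effects["sex"] * sex
    if (!is.null(cfg$causal)) {
      miss <- setdiff(cfg$causal$variant_id, geno$variants$id)
      if (length(miss)) stop("causal variant(s) absent from genotypes: ",
                             paste(miss, collapse = ", "))
      D <- geno$dosage[, cfg$causal$variant_id, drop = FALSE]
      D[is.na(D)] <- 0
      fixed <- fixed + drop(D %*% cfg$causal$beta)
    }
    if (!is.null(cfg$ancestry_loci)) {
      if (is.null(ancestry)) stop("ancestry_loci configured but no local ancestry given")
      for (r in seq_len(nrow(cfg$ancestry_loci))) {
        ad <- ancestry_dosage(ancestry, cfg$ancestry_loci$population[r])
        j <- match(cfg$ancestry_loci$variant_id[r], geno$variants$id)
        fixed <- fixed + cfg$ancestry_loci$beta[r] * ad[, j]
      }
    }
    gpoly <- rep(0, n)
    if (cfg$sigma_g2 > 0) {
      Phi <- pedigree_kinship(ped)[ids, ids]
      L <- chol(2 * Phi * cfg$sigma_g2)
      gpoly <- drop(crossprod(L, rnorm(n)))
    }
    out <- data.frame(
      sample = rep(ids, cfg$n_visits),
      visit = rep(seq_len(cfg$n_visits), each = n),
      med = rep(med, cfg$n_visits), smoke = rep(smoke, cfg$n_visits),
      sex = rep(sex, cfg$n_visits), stringsAsFactors = FALSE)
    out$age <- rep(ages0, cfg$n_visits) + (out$visit - 1) * cfg$visit_increment
    out$trait <- rep(fixed + gpoly, cfg$n_visits) +
      rnorm(nrow(out), 0, sqrt(cfg$sigma_e2_curve(out$age)))
    out[order(out$sample, out$visit), c("sample", "visit", "age", "trait",
                                        "med", "smoke", "sex")]
  })
}

#' Realized global ancestry proportions
#'
#' Per sample and population: the fraction of the diploid genome assigned to
#' that population. Uses exact tract lengths when tracts are available,
#' otherwise the per-variant average of ancestry dosage / 2.
#'
#' @param la a [local_ancestry()]
#' @return samples x populations matrix of proportions (rows sum to 1)
#' @export
global_ancestry_from_local <- function(la) {
  K <- length(la$pop_labels)
  n <- nrow(la$anc1)
  out <- matrix(0, n, K, dimnames = list(la$samples, la$pop_labels))
  if (!is.null(la$tracts)) {
    L <- la$length_cM
    for (i in seq_len(n)) {
      for (h in c("h1", "h2")) {
        tr <- la$tracts[[i]][[h]]
        cov <- sum(tr$end_cM - tr$start_cM)
        if (abs(cov - L) > 1e-8)
          stop("haplotype ", h, " of sample ", la$samples[i],
               " leaves an uncovered gap of ", signif(L - cov, 3), " cM")
        len <- tapply(tr$end_cM - tr$start_cM, factor(tr$pop, levels = seq_len(K)), sum)
        len[is.na(len)] <- 0
        out[i, ] <- out[i, ] + len / (2 * L)
      }
    }
  } else {
    for (k in seq_len(K)) {
      out[, k] <- (rowMeans(la$anc1 == k) + rowMeans(la$anc2 == k)) / 2
    }
  }
  out
}
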