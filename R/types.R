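#' Construct a genotype matrix
#'
#' Container for additive genotypes (counts of the alternate allele, 0/1/2 or
#' `NA` for missing) together with per-variant metadata.
#'
#' @param dosage integer/numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids.
#' @param variants data frame with columns `id`, `chrom`, `bp`, `cM`, `ref`,
#'   `alt`, one row per column of `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  need <- c("id", "chrom", "bp", "cM", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table lacks columns: ", paste(miss, collapse = ", "))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  for (ch in unique(variants$chrom)) {
    bp <- variants$bp[variants$chrom == ch]
    if (is.unsorted(bp, strictly = TRUE))
      stop("bp positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = as.data.frame(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "variants\n")
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param g a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_variants_of <- function(g) ncol(g$dosage)

#' Subset a genotype matrix by variant index or id
#' @param g a `genotype_matrix`
#' @param keep integer indices or character variant ids to retain
#' @return a `genotype_matrix`
#' @export
subset_variants <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$variants$id)
  stopifnot(!anyNA(keep))
  genotype_matrix(g$dosage[, keep, drop = FALSE], g$variants[keep, , drop = FALSE])
}

#' Construct a pedigree table
#'
#' @param id,family character vectors of individual and family ids.
#' @param father,mother parent ids; `NA` for founders. Parents, when given,
#'   must be present in `id`, and no individual may be its own ancestor.
#' @param sex 1 = male, 2 = female (PED convention).
#' @return A data frame of class `pedigree` with columns
#'   `id`, `family`, `father`, `mother`, `sex`.
#' @export
pedigree <- function(id, family, father, mother, sex) {
  ped <- data.frame(id = as.character(id), family = as.character(family),
                    father = as.character(father), mother = as.character(mother),
                    sex = as.integer(sex), stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  for (col in c("father", "mother")) {
    known <- !is.na(ped[[col]])
    if (!all(ped[[col]][known] %in% ped$id))
      stop("pedigree references unknown ", col, " id(s)")
  }
  ord <- pedigree_order(ped)   # errors on cycles
  attr(ped, "order") <- ord
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# topological order (parents before children); detects cycles
pedigree_order <- function(ped) {
  n <- nrow(ped)
  depth <- rep(NA_integer_, n)
  idx <- setNames(seq_len(n), ped$id)
  get_depth <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (seen[i]) stop("pedigree contains a cycle involving ", ped$id[i])
    seen[i] <- TRUE
    f <- ped$father[i]; m <- ped$mother[i]
    d <- 0L
    if (!is.na(f)) d <- max(d, get_depth(idx[[f]], seen) + 1L)
    if (!is.na(m)) d <- max(d, get_depth(idx[[m]], seen) + 1L)
    depth[i] <<- d
    d
  }
  for (i in seq_len(n)) get_depth(i, rep(FALSE, n))
  order(depth, seq_len(n))
}

#' Founder indicator for a pedigree
#' @param ped a `pedigree`
#' @return logical vector, `TRUE` where both parents are missing
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Construct a genetic map
#'
#' Framework points for piecewise-linear bp-to-cM interpolation.
#'
#' @param chrom chromosome label per point
#' @param bp,cM physical and map positions; jointly non-decreasing within
#'   chromosome, at least two points per chromosome
#' @return data frame of class `genetic_map`
#' @export
genetic_map <- function(chrom, bp, cM) {
  m <- data.frame(chrom = as.character(chrom), bp = as.numeric(bp), cM = as.numeric(cM))
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (nrow(sub) < 2) stop("genetic map needs >= 2 points for chromosome ", ch)
    if (is.unsorted(sub$bp) || is.unsorted(sub$cM))
      stop("bp and cM must be non-decreasing within chromosome ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Construct a local-ancestry object
#'
#' Per-haplotype population-of-origin along the genetic map. Tracts (exact
#' breakpoints in cM) are stored when the simulator ran with linkage; the
#' per-variant label matrices are always available.
#'
#' @param anc1,anc2 integer matrices (samples x variants) of population
#'   indices for haplotype 1 and 2.
#' @param pop_labels population names, indexed by the label matrices.
#' @param map_cM variant cM positions (length = ncol(anc1)).
#' @param length_cM total map length in cM.
#' @param tracts optional list (per sample) of `list(h1=, h2=)` data frames
#'   with columns `start_cM`, `end_cM`, `pop`.
#' @param chrom chromosome label.
#' @return object of class `local_ancestry`
#' @export
local_ancestry <- function(anc1, anc2, pop_labels, map_cM, length_cM,
                           tracts = NULL, chrom = "1") {
  stopifnot(all(dim(anc1) == dim(anc2)), length(map_cM) == ncol(anc1))
  structure(list(anc1 = anc1, anc2 = anc2, pop_labels = pop_labels,
                 map_cM = map_cM, length_cM = length_cM, tracts = tracts,
                 chrom = chrom, samples = rownames(anc1)),
            class = "local_ancestry")
}

#' Per-variant ancestry dosage for one population
#'
#' @param la a `local_ancestry` object
#' @param population population label
#' @return samples x variants matrix of 0/1/2 copies of the named ancestry
#' @export
ancestry_dosage <- function(la, population) {
  k <- match(population, la$pop_labels)
  if (is.na(k)) stop("population '", population, "' absent from local ancestry")
  d <- (la$anc1 == k) + (la$anc2 == k)
  storage.mode(d) <- "integer"
  rownames(d) <- la$samples
  d
}
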