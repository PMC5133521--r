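#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction,
#' `theta = (1 - exp(-2 d / 100)) / 2`, and back.
#'
#' @param d map distance in cM (>= 0)
#' @return recombination fraction in [0, 0.5)
#' @export
haldane_theta <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane_theta
#' @param theta recombination fraction, strictly below 0.5
#' @export
haldane_inverse <- function(theta) {
  if (any(theta < 0 | theta >= 0.5)) stop("theta must lie in [0, 0.5)")
  -50 * log(1 - 2 * theta)
}

#' Interpolate cM positions from a framework map
#'
#' Piecewise-linear interpolation between flanking framework points; targets
#' beyond the framework are clamped to the boundary cM value (no slope
#' extrapolation, avoiding negative or runaway map positions).
#'
#' @param chrom chromosome label per target
#' @param bp target bp positions, sorted within chromosome
#' @param map a [genetic_map()]
#' @return numeric cM positions
#' @export
interpolate_cM <- function(chrom, bp, map) {
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) == 0) stop("chromosome ", ch, " absent from genetic map")
    sel <- chrom == ch
    out[sel] <- approx(sub$bp, sub$cM, xout = bp[sel], rule = 2, ties = "ordered")$y
  }
  out
}

#' Write genotypes as VCF 4.2
#'
#' Emits a minimal plain-text VCF with a GT field. Unphased by default;
#' passing `haplotypes` (list with `h1`, `h2` allele matrices) writes phased
#' genotypes that preserve the simulated haplotypes.
#'
#' @param g a [genotype_matrix()]
#' @param path output file
#' @param haplotypes optional phased alleles from [drop_genes()]
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path, haplotypes = NULL) {
  v <- g$variants
  samples <- rownames(g$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixkin",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (is.null(haplotypes)) {
    gt_codes <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(g$dosage), ncol(g$dosage))
    ok <- !is.na(g$dosage)
    gt[ok] <- gt_codes[g$dosage[ok] + 1L]
  } else {
    gt <- matrix(paste0(haplotypes$h1, "|", haplotypes$h2),
                 nrow(g$dosage), ncol(g$dosage))
    gt[is.na(haplotypes$h1) | is.na(haplotypes$h2)] <- ".|."
  }
  lines <- vapply(seq_len(nrow(v)), function(s) {
    paste(c(v$chrom[s], v$bp[s], v$id[s], v$ref[s], v$alt[s], ".", "PASS",
            ".", "GT", gt[, s]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses a VCF 4.x with a GT field via the vcfR reader and converts to
#' alternate-allele dosage. Missing genotypes (`./.` or `.|.`) become `NA`.
#' Multi-allelic records are rejected with an error naming the site
#' (default) or dropped, per `multiallelic`.
#'
#' @param path VCF file
#' @param multiallelic `"reject"` or `"drop"`
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, multiallelic = c("reject", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "reject")
      stop("multi-allelic site(s) not supported: ",
           paste(fix$ID[multi], collapse = ", "))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF lacks a GT field")
  count_alt <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (length(al) == 0 || anyNA(al) || any(al == ".")) return(NA_integer_)
      sum(as.integer(al))
    }, integer(1))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))
  dos <- t(dos)  # samples x variants
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM, bp = as.numeric(fix$POS),
                         cM = NA_real_, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  storage.mode(dos) <- "integer"
  genotype_matrix(dos, variants)
}

#' Read/write 6-column PED/FAM pedigree text
#'
#' Columns: family, individual, father, mother, sex, phenotype. `0` encodes
#' a missing parent.
#'
#' @param ped a [pedigree()]
#' @param path file path
#' @return `read_ped` returns a [pedigree()]; `write_ped` returns `path`.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(ped$family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    ped$sex, 0)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  pedigree(id = tab[[2]], family = tab[[1]],
           father = ifelse(tab[[3]] == "0", NA, tab[[3]]),
           mother = ifelse(tab[[4]] == "0", NA, tab[[4]]),
           sex = tab[[5]])
}

#' Read/write a 3-column genetic map (chrom, bp, cM)
#' @param map a [genetic_map()]
#' @param path file path
#' @return `read_genetic_map` returns a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(map)[, c("chrom", "bp", "cM")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  genetic_map(tab$chrom, tab$bp, tab$cM)
}

#' Read/write phenotype CSV (sample, visit, age, trait, med, smoke, sex)
#' @param pheno long-format phenotype data frame
#' @param path file path
#' @return `read_phenotypes` returns the data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}

#' Write local-ancestry tracts as TSV
#'
#' Columns: sample, haplotype (0/1), chrom, start_cM, end_cM, population.
#' Requires tract-resolved ancestry (simulation with `linkage = TRUE`).
#'
#' @param la a [local_ancestry()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_ancestry_tracts <- function(la, path) {
  if (is.null(la$tracts)) stop("no tract representation available (unlinked simulation)")
  rows <- list()
  for (i in seq_along(la$tracts)) {
    for (h in 1:2) {
      tr <- la$tracts[[i]][[c("h1", "h2")[h]]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = la$samples[i], haplotype = h - 1L, chrom = la$chrom,
        start_cM = tr$start_cM, end_cM = tr$end_cM,
        population = la$pop_labels[tr$pop])
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset variants to genomic intervals
#'
#' Keeps variants whose 1-based position falls inside any BED interval
#' (0-based half-open; a variant at 1-based position p is inside `[a, b)`
#' iff `a <= p - 1 < b`). Overlapping intervals do not duplicate variants;
#' variant order is preserved.
#'
#' @param g a [genotype_matrix()]
#' @param bed path to a BED file
#' @return a [genotype_matrix()] restricted to the intervals
#' @export
subset_by_intervals <- function(g, bed) {
  iv <- rtracklayer::import(bed, format = "BED")
  if (length(iv) == 0) return(subset_variants(g, integer(0)))
  vr <- GenomicRanges::GRanges(g$variants$chrom,
                               IRanges::IRanges(g$variants$bp, width = 1))
  hit <- IRanges::overlapsAny(vr, iv)
  subset_variants(g, which(hit))
}
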