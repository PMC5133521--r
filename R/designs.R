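#' Per-variant allele-frequency summaries
#'
#' Computes the sample alternate-allele frequency and MAF over all samples
#' with non-missing genotypes, the founder MAF over pedigree founders only,
#' and a monomorphic flag. Per-population alternate-allele frequencies are
#' attached when a `pop_freqs` truth/reference table is supplied.
#'
#' @param g a [genotype_matrix()]
#' @param ped optional [pedigree()] for founder MAF
#' @param pop_freqs optional `pop_freqs` object or pops x variants matrix
#' @return data frame of class `variant_stats`: `id`, `alt_freq`, `maf`,
#'   `founder_maf`, `monomorphic`, plus `pop_<label>` frequency columns.
#' @export
compute_variant_stats <- function(g, ped = NULL, pop_freqs = NULL) {
  dos <- g$dosage
  f <- colMeans(dos, na.rm = TRUE) / 2
  n_obs <- colSums(!is.na(dos))
  f[n_obs == 0] <- NA_real_
  maf <- pmin(f, 1 - f)
  out <- data.frame(id = g$variants$id, alt_freq = f, maf = maf,
                    founder_maf = NA_real_,
                    monomorphic = !is.na(maf) & maf == 0,
                    stringsAsFactors = FALSE)
  if (!is.null(ped)) {
    fids <- ped$id[is_founder(ped)]
    fids <- intersect(fids, rownames(dos))
    if (length(fids) == 0) {
      warning("no founders with genotypes; founder MAF unavailable")
    } else {
      ff <- colMeans(dos[fids, , drop = FALSE], na.rm = TRUE) / 2
      out$founder_maf <- pmin(ff, 1 - ff)
    }
  }
  if (!is.null(pop_freqs)) {
    fr <- if (inherits(pop_freqs, "pop_freqs")) pop_freqs$freq else pop_freqs
    stopifnot(ncol(fr) == nrow(out))
    for (k in seq_len(nrow(fr)))
      out[[paste0("pop_", rownames(fr)[k] %||% k)]] <- fr[k, ]
  }
  class(out) <- c("variant_stats", "data.frame")
  out
}

#' Greedy windowed LD pruning
#'
#' Walks variants left to right in genomic order; a variant is dropped if
#' its squared Pearson dosage correlation with any retained variant within
#' `window` positions exceeds `r2_max` (so every retained pair within a
#' window satisfies `r^2 <= r2_max`). Zero-variance (monomorphic) variants
#' are removed up front.
#'
#' @param g a [genotype_matrix()]
#' @param r2_max squared-correlation threshold in (0, 1]
#' @param window window size in variant count (>= 2)
#' @param step reserved for compatibility; the greedy walk advances one
#'   variant at a time
#' @return character vector of retained variant ids (genomic order)
#' @export
ld_prune <- function(g, r2_max = 0.2, window = 50, step = 5) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  if (window < 2) stop("window must be >= 2")
  dos <- g$dosage
  v <- apply(dos, 2, var, na.rm = TRUE)
  cand <- which(!is.na(v) & v > 0)
  kept <- integer(0)
  for (j in cand) {
    near <- kept[kept > j - window]
    ok <- TRUE
    for (i in near) {
      r <- suppressWarnings(cor(dos[, i], dos[, j], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  g$variants$id[kept]
}

design_result <- function(name, kept, params) {
  structure(list(design = name, kept = kept, params = params),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("design:", x$design, "-", length(x$kept), "variants kept\n")
  invisible(x)
}

#' Agnostic marker design: every k-th variant
#'
#' Keeps the variants at indices 0, k, 2k, ... (0-based) of the post-prune
#' genomic ordering, emulating an allele-frequency-agnostic thinning of a
#' sequencing panel.
#'
#' @param ids variant ids in genomic order (after the first LD prune)
#' @param stride k (default 100; `k = 1` keeps everything)
#' @return a `design_result`
#' @export
design_agnostic <- function(ids, stride = 100) {
  if (stride < 1) stop("stride must be >= 1")
  design_result("agnostic", ids[seq(1, length(ids), by = stride)],
                list(stride = stride))
}

#' Selective marker design: common variants only
#'
#' Keeps variants with sample MAF greater than or equal to `maf_min`
#' (inclusive boundary).
#'
#' @param stats a `variant_stats` table
#' @param maf_min MAF cutoff (default 0.05)
#' @return a `design_result`
#' @export
design_selective <- function(stats, maf_min = 0.05) {
  keep <- !is.na(stats$maf) & stats$maf >= maf_min & !stats$monomorphic
  design_result("selective", stats$id[keep], list(maf_min = maf_min))
}

#' Homogenizing marker design: frequency-homogeneous variants
#'
#' Keeps variant s iff the spread of its per-population alternate-allele
#' frequencies, relative to their unweighted mean, is small:
#' `(max_k f_ks - min_k f_ks) / mean_k f_ks <= ratio_max`. Variants with
#' zero mean frequency (or monomorphic in the sample) are excluded. This
#' selects markers that are minimally ancestry-informative, reducing the
#' structure sensitivity of downstream kinship estimation.
#'
#' @param stats a `variant_stats` table carrying `pop_*` frequency columns
#' @param ratio_max spread/mean cutoff (default 2)
#' @return a `design_result`
#' @export
design_homogenizing <- function(stats, ratio_max = 2) {
  pop_cols <- grep("^pop_", names(stats), value = TRUE)
  if (length(pop_cols) < 2)
    stop("homogenizing design needs per-population frequencies for >= 2 populations")
  fr <- as.matrix(stats[, pop_cols])
  fbar <- rowMeans(fr)
  spread <- apply(fr, 1, max) - apply(fr, 1, min)
  ratio <- ifelse(fbar > 0, spread / fbar, Inf)
  keep <- ratio <= ratio_max & !stats$monomorphic & !is.na(stats$maf)
  design_result("homogenizing", stats$id[keep], list(ratio_max = ratio_max))
}

#' The full marker-selection pipeline of one design
#'
#' Reproduces the ordering prune(r2 <= r2_first) -> design filter ->
#' prune(r2 <= r2_second), so the final panel satisfies both the design
#' predicate and the tighter final LD bound.
#'
#' @param g a [genotype_matrix()]
#' @param design one of `"agnostic"`, `"selective"`, `"homogenizing"`
#' @param ped,pop_freqs passed to [compute_variant_stats()]
#' @param r2_first,r2_second the two LD thresholds (defaults 0.2 and 0.1)
#' @param window LD-pruning window
#' @param ... design-specific parameters (`stride`, `maf_min`, `ratio_max`)
#' @return a `design_result` whose `kept` ids satisfy the composition
#' @export
design_pipeline <- function(g, design = c("agnostic", "selective", "homogenizing"),
                            ped = NULL, pop_freqs = NULL,
                            r2_first = 0.2, r2_second = 0.1, window = 50, ...) {
  design <- match.arg(design)
  ids1 <- ld_prune(g, r2_max = r2_first, window = window)
  g1 <- subset_variants(g, ids1)
  pf1 <- pop_freqs
  if (!is.null(pf1)) {
    fr <- if (inherits(pf1, "pop_freqs")) pf1$freq else pf1
    pf1 <- fr[, match(ids1, g$variants$id), drop = FALSE]
  }
  stats <- compute_variant_stats(g1, ped, pf1)
  dr <- switch(design,
    agnostic = design_agnostic(ids1, ...),
    selective = design_selective(stats, ...),
    homogenizing = design_homogenizing(stats, ...))
  g2 <- subset_variants(g, dr$kept)
  ids2 <- ld_prune(g2, r2_max = r2_second, window = window)
  design_result(design, ids2,
                c(dr$params, list(r2_first = r2_first, r2_second = r2_second,
                                  window = window)))
}
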