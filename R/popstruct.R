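grm_prep <- function(g) {
  dos <- g$dosage
  f <- colMeans(dos, na.rm = TRUE) / 2
  # count minor alleles: flip columns where the alternate allele is major
  flip <- is.finite(f) & f > 0.5
  dos[, flip] <- 2L - dos[, flip]
  p <- pmin(f, 1 - f)
  list(dos = dos, p = p)
}

#' Genetic relationship matrix, ratio-of-sums normalization
#'
#' `psi_ij = sum_s (G_is - 2 p_s)(G_js - 2 p_s) / sum_s 2 p_s (1 - p_s)`
#' with `G` counted in minor alleles and `p_s` the sample MAF. A single
#' shared denominator makes the estimator insensitive to low-frequency
#' variants (no per-marker division blow-up). Missing dosages are
#' mean-imputed (`2 p_s`) inside the construction only.
#'
#' @param g a [genotype_matrix()]
#' @return list of class `grm`: `psi` (samples x samples), `normalization`,
#'   `S` (variants used), `p` (MAFs used)
#' @export
grm_ratio_of_sums <- function(g) {
  pr <- grm_prep(g)
  use <- which(is.finite(pr$p) & pr$p > 0)
  if (length(use) == 0) stop("all variants monomorphic: GRM denominator is zero")
  dos <- pr$dos[, use, drop = FALSE]; p <- pr$p[use]
  C <- sweep(dos, 2, 2 * p)
  C[is.na(C)] <- 0
  psi <- tcrossprod(C) / sum(2 * p * (1 - p))
  structure(list(psi = psi, normalization = "ratio_of_sums",
                 S = length(use), p = p), class = "grm")
}

#' Genetic relationship matrix, per-marker standardization
#'
#' `psi_ij = (1/S) sum_s (G_is - 2 p_s)(G_js - 2 p_s) / (2 p_s (1 - p_s))`
#' (EIGENSTRAT-style scaling). Variants with MAF below `maf_floor`
#' (default `1 / (2 n)`) are excluded to avoid division blow-up.
#'
#' @param g a [genotype_matrix()]
#' @param maf_floor minimum MAF for inclusion
#' @return a `grm` (see [grm_ratio_of_sums()])
#' @export
grm_per_marker <- function(g, maf_floor = NULL) {
  pr <- grm_prep(g)
  maf_floor <- maf_floor %||% (1 / (2 * nrow(g$dosage)))
  use <- which(is.finite(pr$p) & pr$p >= maf_floor & pr$p > 0)
  if (length(use) == 0) stop("no variants pass the MAF floor")
  dos <- pr$dos[, use, drop = FALSE]; p <- pr$p[use]
  Z <- sweep(dos, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  psi <- tcrossprod(Z) / length(use)
  structure(list(psi = psi, normalization = "per_marker",
                 S = length(use), p = p), class = "grm")
}

#' PCA of a genetic relationship matrix
#'
#' Eigendecomposition of the (optionally column/row-centered) GRM.
#' Eigenvector signs are fixed canonically: the largest-magnitude
#' coordinate of each component is positive.
#'
#' @param grm a `grm` object or a symmetric matrix
#' @param n_components number of components to return
#' @param center double-center the GRM before decomposition (default
#'   `FALSE`: the raw matrix is decomposed)
#' @return list of class `grm_pca`: `values` (all eigenvalues, descending),
#'   `scores` (samples x n_components, eigenvectors scaled by sqrt
#'   eigenvalue where positive)
#' @export
pca_grm <- function(grm, n_components = 10, center = FALSE) {
  psi <- if (inherits(grm, "grm")) grm$psi else grm
  if (!isSymmetric(unname(psi), tol = 1e-8)) stop("GRM must be symmetric")
  if (center) {
    n <- nrow(psi)
    J <- diag(n) - matrix(1 / n, n, n)
    psi <- J %*% psi %*% J
  }
  ee <- eigen(psi, symmetric = TRUE)
  k <- min(n_components, ncol(ee$vectors))
  vec <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(pmax(ee$values[seq_len(k)], 0)), "*")
  rownames(scores) <- rownames(psi)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(values = ee$values, scores = scores, vectors = vec),
            class = "grm_pca")
}

#' Ancestry capture by principal components
#'
#' Ordinary least-squares regression of each ancestry proportion on an
#' intercept plus the top `n_pcs` PC scores; returns the coefficient of
#' determination per ancestry component.
#'
#' @param pca a `grm_pca` (or a score matrix)
#' @param proportions samples x populations matrix of ancestry proportions
#' @param n_pcs number of leading PCs to use (e.g. 10 or 20)
#' @return named numeric vector of R-squared values (NA for a constant
#'   response, which leaves R-squared undefined)
#' @export
ancestry_r2 <- function(pca, proportions, n_pcs = 10) {
  scores <- if (inherits(pca, "grm_pca")) pca$scores else pca
  n_pcs <- min(n_pcs, ncol(scores))
  X <- scores[, seq_len(n_pcs), drop = FALSE]
  if (nrow(X) < n_pcs + 2) stop("need at least n_pcs + 2 samples")
  apply(as.matrix(proportions), 2, function(y) {
    if (var(y) == 0) return(NA_real_)
    summary(lm(y ~ X))$r.squared
  })
}

#' Write a GRM as a square whitespace-delimited matrix with an id header
#' @param grm a `grm`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_grm <- function(grm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(grm$psi), collapse = " "), con)
  write.table(grm$psi, con, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
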