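#' Partition samples into unrelated and related sets
#'
#' Greedy selection on a kinship matrix: iteratively remove the individual
#' with the most pairs above `kin_threshold` (ties broken by removing the
#' candidate with the largest total kinship to the remaining set, i.e.
#' lower total kinship retained, then by id order) until no retained pair
#' exceeds the threshold.
#'
#' @param kin symmetric kinship matrix with sample ids as dimnames
#' @param kin_threshold relatedness cutoff (default 0.025, ~3rd/4th degree)
#' @return list with `unrelated` and `related` id vectors
#' @export
pcair_partition <- function(kin, kin_threshold = 0.025) {
  if (is.null(dim(kin)) || nrow(kin) == 0) stop("empty kinship matrix")
  ids <- rownames(kin) %||% as.character(seq_len(nrow(kin)))
  A <- kin > kin_threshold
  diag(A) <- FALSE
  keep <- rep(TRUE, nrow(kin))
  repeat {
    cnt <- rowSums(A[, keep, drop = FALSE]) * keep
    if (max(cnt) == 0) break
    cand <- which(cnt == max(cnt))
    if (length(cand) > 1) {
      tot <- rowSums(kin[cand, keep, drop = FALSE]) - diag(kin)[cand]
      cand <- cand[tot == max(tot)]
    }
    keep[cand[1]] <- FALSE
  }
  list(unrelated = ids[keep], related = ids[!keep])
}

#' PCs of population structure from an unrelated subset, projected to all
#'
#' Standardizes genotypes with allele frequencies computed on the unrelated
#' set (EIGENSTRAT scaling), takes the SVD on the unrelated samples, and
#' projects every sample onto the variant loadings, so family structure
#' does not contaminate the ancestry axes.
#'
#' @param g a [genotype_matrix()]
#' @param unrelated ids of the unrelated set (e.g. from [pcair_partition()])
#' @param n_pcs number of components
#' @return list with `scores` (all samples x n_pcs), `d` (singular values),
#'   `unrelated`
#' @export
pcair_scores <- function(g, unrelated, n_pcs = 10) {
  dos <- g$dosage
  u <- match(unrelated, rownames(dos))
  stopifnot(!anyNA(u))
  p <- colMeans(dos[u, , drop = FALSE], na.rm = TRUE) / 2
  ok <- is.finite(p) & p > 0 & p < 1
  p <- p[ok]
  Z <- sweep(dos[, ok, drop = FALSE], 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z[u, , drop = FALSE], nu = 0, nv = n_pcs)
  scores <- Z %*% sv$v
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, d = sv$d[seq_len(n_pcs)], unrelated = unrelated)
}

#' PC-adjusted moment estimator of kinship (individual-specific frequencies)
#'
#' For every marker, genotype is regressed on an intercept plus `n_pcs`
#' PCs by least squares over the unrelated set; the fitted values for all
#' samples, halved and truncated to `[eps, 1 - eps]`, give
#' individual-specific allele frequencies `mu_is`. Kinship is then
#' `phi_ij = sum_s (g_is - 2 mu_is)(g_js - 2 mu_js) /
#'           (4 sum_s sqrt(mu_is (1-mu_is) mu_js (1-mu_js)))`,
#' which removes the ancestry-driven bias of classical GRM kinship in
#' structured or admixed samples.
#'
#' @param g a [genotype_matrix()]
#' @param pcs sample x PC score matrix (all samples; e.g.
#'   [pcair_scores()]`$scores`)
#' @param unrelated ids of the unrelated training set
#' @param n_pcs number of PCs used in the frequency model
#' @param pairs optional 2-column index matrix; default all pairs
#' @param eps truncation bound for `mu`; default `1 / (2 n)`
#' @return kinship data frame (`id1`, `id2`, `kinship`, ...)
#' @export
pcrelate <- function(g, pcs, unrelated, n_pcs = ncol(pcs), pairs = NULL,
                     eps = NULL) {
  dos <- g$dosage
  n <- nrow(dos)
  eps <- eps %||% (1 / (2 * n))
  X <- cbind(1, pcs[, seq_len(n_pcs), drop = FALSE])
  u <- match(unrelated, rownames(dos))
  stopifnot(!anyNA(u))
  Gu <- dos[u, , drop = FALSE]
  Gu[is.na(Gu)] <- NA
  # per-marker least squares over the unrelated set (complete rows per marker)
  Xu <- X[u, , drop = FALSE]
  B <- tryCatch(solve(crossprod(Xu), crossprod(Xu, ifelse(is.na(Gu), 0, Gu))),
                error = function(e) stop("PC design is rank deficient: ", conditionMessage(e)))
  if (anyNA(Gu)) {
    # redo markers with missingness marker-by-marker on complete rows
    for (s in which(colSums(is.na(Gu)) > 0)) {
      cc <- !is.na(Gu[, s])
      B[, s] <- qr.coef(qr(Xu[cc, , drop = FALSE]), Gu[cc, s])
    }
  }
  mu <- (X %*% B) / 2
  mu[mu < eps] <- eps
  mu[mu > 1 - eps] <- 1 - eps
  R <- dos - 2 * mu
  R[is.na(R)] <- 0
  V <- sqrt(mu * (1 - mu))
  Vm <- V
  Vm[is.na(dos)] <- 0   # drop missing genotypes from both sums
  num <- tcrossprod(R)
  den <- 4 * tcrossprod(Vm)
  phi <- num / den
  phi[den == 0] <- NA_real_
  if (is.null(pairs)) pairs <- all_pairs(n)
  M <- !is.na(dos); storage.mode(M) <- "double"
  kin_df(g, pairs, phi[pairs], "pcrelate", n_markers = tcrossprod(M)[pairs])
}
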