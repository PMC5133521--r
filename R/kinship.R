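#' Pedigree-based kinship matrix
#'
#' Recursive computation over a topologically ordered pedigree with
#' founders assumed mutually unrelated and non-inbred:
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2`, and for j processed
#' before i, `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2`.
#'
#' @param ped a [pedigree()] (acyclic; validated at construction)
#' @return symmetric matrix of kinship coefficients, self-kinship >= 0.5
#' @export
pedigree_kinship <- function(ped) {
  ord <- attr(ped, "order") %||% pedigree_order(ped)
  n <- nrow(ped)
  Phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- setNames(seq_len(n), ped$id)
  done <- integer(0)
  for (i in ord) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (is.na(f)) {
      Phi[i, i] <- 0.5
    } else {
      fi <- idx[[f]]; mi <- idx[[m]]
      Phi[i, i] <- 0.5 * (1 + Phi[fi, mi])
      if (length(done)) {
        Phi[i, done] <- 0.5 * (Phi[fi, done] + Phi[mi, done])
        Phi[done, i] <- Phi[i, done]
      }
    }
    done <- c(done, i)
  }
  Phi
}

#' Expected kinship and relationship degree from a pedigree
#'
#' Maps exact pedigree kinship values to the five benchmark categories:
#' 0.25 -> 1st, 0.125 -> 2nd, 0.0625 -> 3rd, 0.03125 -> 4th, 0 ->
#' unrelated. Pairs with other (more distant but nonzero) kinship get `NA`
#' and are excluded from classification-rate tables.
#'
#' @param phi numeric kinship value(s)
#' @return character vector of degrees
#' @export
true_degree <- function(phi) {
  lv <- c(0.25, 0.125, 0.0625, 0.03125, 0)
  nm <- c("1st", "2nd", "3rd", "4th", "unrelated")
  out <- rep(NA_character_, length(phi))
  for (k in seq_along(lv)) out[abs(phi - lv[k]) < 1e-9] <- nm[k]
  out
}

#' Classify a kinship estimate into a relationship degree
#'
#' Rounds to the nearest expected kinship among
#' `{0.25, 0.125, 0.0625, 0.03125, 0}`; exact midpoint ties go to the more
#' distant degree (conservative against overstating relatedness).
#'
#' @param phi_hat kinship estimate(s), finite
#' @return character vector: `"1st"`, `"2nd"`, `"3rd"`, `"4th"`, `"unrelated"`
#' @export
classify_relationship <- function(phi_hat) {
  lv <- c(0.25, 0.125, 0.0625, 0.03125, 0)
  nm <- c("1st", "2nd", "3rd", "4th", "unrelated")
  vapply(phi_hat, function(x) {
    if (!is.finite(x)) return(NA_character_)
    d <- abs(x - lv)
    # ties: last index among minima = smaller expected kinship
    nm[max(which(d == min(d)))]
  }, character(1))
}

#' Rates of successfully classified relationships
#'
#' For each true degree, the fraction of pairs whose called degree equals
#' the truth. Degrees with no pairs are reported `NA` (undefined), not 0.
#'
#' @param truth,called character vectors of true and called degrees
#' @return data frame with `degree`, `n_pairs`, `rate`
#' @export
classification_table <- function(truth, called) {
  keep <- !is.na(truth)
  truth <- truth[keep]; called <- called[keep]
  degs <- c("1st", "2nd", "3rd", "4th", "unrelated")
  data.frame(degree = degs,
             n_pairs = vapply(degs, function(d) sum(truth == d), integer(1)),
             rate = vapply(degs, function(d) {
               n <- sum(truth == d)
               if (n == 0) NA_real_ else sum(truth == d & called == d) / n
             }, numeric(1)),
             row.names = NULL)
}

all_pairs <- function(n) {
  p <- combn(n, 2)
  cbind(i = p[1, ], j = p[2, ])
}

kin_df <- function(g, pairs, phi, estimator, extra = NULL, n_markers) {
  ids <- rownames(g$dosage)
  out <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                    kinship = phi, n_markers = n_markers,
                    estimator = estimator, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' KING-robust kinship estimator
#'
#' Between-family robust estimator from heterozygote/opposite-homozygote
#' counts over markers non-missing in both members of a pair:
#' `phi = 1/2 + (2 N_AaAa - 4 N_AAaa - N_Aa_i - N_Aa_j) / (4 min(N_Aa_i, N_Aa_j))`.
#' The `"sum"` dialect replaces the denominator with
#' `2 (N_Aa_i + N_Aa_j)`. Pairs where either member has no heterozygous
#' marker are undefined (`NA`).
#'
#' @param g a [genotype_matrix()]
#' @param pairs optional 2-column index matrix; default all pairs
#' @param denominator `"min"` (primary) or `"sum"`
#' @return long-format kinship data frame (`id1`, `id2`, `kinship`,
#'   `n_markers`, `estimator`)
#' @export
king_robust <- function(g, pairs = NULL, denominator = c("min", "sum")) {
  denominator <- match.arg(denominator)
  dos <- g$dosage
  n <- nrow(dos)
  M <- !is.na(dos); storage.mode(M) <- "double"
  het <- (dos == 1L) & !is.na(dos); storage.mode(het) <- "double"
  hom0 <- (dos == 0L) & !is.na(dos); storage.mode(hom0) <- "double"
  hom2 <- (dos == 2L) & !is.na(dos); storage.mode(hom2) <- "double"
  Naa <- tcrossprod(het)                       # double-heterozygote count
  Nopp <- tcrossprod(hom0, hom2); Nopp <- Nopp + t(Nopp)
  Hi <- tcrossprod(het, M)                     # het count of i over pair-complete markers
  Hj <- t(Hi)
  denom <- if (denominator == "min") 4 * pmin(Hi, Hj) else 2 * (Hi + Hj)
  phi <- 0.5 + (2 * Naa - 4 * Nopp - Hi - Hj) / denom
  phi[denom == 0] <- NA_real_
  if (is.null(pairs)) pairs <- all_pairs(n)
  kin_df(g, pairs, phi[pairs], "king",
         n_markers = tcrossprod(M)[pairs])
}

# per-marker genotype-pair probabilities given IBD state d, alt freq p;
# dosage counts alt alleles, HWE within the (assumed homogeneous) sample
ibd_pair_tables <- function(p) {
  q <- 1 - p
  gp <- rbind(q^2, 2 * p * q, p^2)            # 3 x S genotype probabilities
  L0 <- array(0, c(3, 3, length(p)))
  L1 <- array(0, c(3, 3, length(p)))
  L2 <- array(0, c(3, 3, length(p)))
  for (a in 1:3) for (b in 1:3) L0[a, b, ] <- gp[a, ] * gp[b, ]
  for (a in 1:3) L2[a, a, ] <- gp[a, ]
  L1[1, 1, ] <- q^3;     L1[3, 3, ] <- p^3
  L1[1, 2, ] <- L1[2, 1, ] <- p * q^2
  L1[3, 2, ] <- L1[2, 3, ] <- p^2 * q
  L1[2, 2, ] <- p * q
  list(L0 = L0, L1 = L1, L2 = L2)
}

#' Method-of-moments IBD estimator
#'
#' Counts identity-by-state (IBS) sharing per pair and solves sequentially
#' for the IBD coefficients using the Hardy-Weinberg expected per-marker
#' IBS probabilities at plug-in sample allele frequencies:
#' `k0 = N_IBS0 / E[N_IBS0 | IBD0]`, `k1` from the IBS1 balance after
#' removing the `k0` contribution, `k2` as the remainder; each clamped to
#' `[0, 1]` and renormalized. `phi = k1/4 + k2/2`.
#'
#' @param g a [genotype_matrix()]
#' @param freqs optional alternate-allele frequencies (default: sample)
#' @param pairs optional 2-column index matrix; default all pairs
#' @return kinship data frame with `k0`, `k1`, `k2` columns
#' @export
mom_ibd <- function(g, freqs = NULL, pairs = NULL) {
  dos <- g$dosage
  n <- nrow(dos)
  p <- freqs %||% (colMeans(dos, na.rm = TRUE) / 2)
  use <- which(is.finite(p) & p > 0 & p < 1)
  dos <- dos[, use, drop = FALSE]; p <- p[use]
  q <- 1 - p
  M <- !is.na(dos); storage.mode(M) <- "double"
  I0 <- (dos == 0L) & !is.na(dos); storage.mode(I0) <- "double"
  I1 <- (dos == 1L) & !is.na(dos); storage.mode(I1) <- "double"
  I2 <- (dos == 2L) & !is.na(dos); storage.mode(I2) <- "double"
  N0 <- tcrossprod(I0, I2); N0 <- N0 + t(N0)                 # IBS0 counts
  N2 <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)     # IBS2 counts
  Ntot <- tcrossprod(M)
  N1 <- Ntot - N0 - N2
  # expected per-pair sums over pairwise-complete markers
  P00 <- 2 * p^2 * q^2
  P10 <- 4 * p^3 * q + 4 * p * q^3
  P11 <- 2 * p^2 * q + 2 * p * q^2
  E00 <- M %*% (t(M) * P00)
  E10 <- M %*% (t(M) * P10)
  E11 <- M %*% (t(M) * P11)
  k0 <- N0 / E00
  k1 <- (N1 - k0 * E10) / E11
  k0 <- pmin(pmax(k0, 0), 1); k1 <- pmin(pmax(k1, 0), 1)
  k2 <- pmin(pmax(1 - k0 - k1, 0), 1)
  tot <- k0 + k1 + k2
  k0 <- k0 / tot; k1 <- k1 / tot; k2 <- k2 / tot
  phi <- k1 / 4 + k2 / 2
  if (is.null(pairs)) pairs <- all_pairs(n)
  kin_df(g, pairs, phi[pairs], "mom",
         extra = data.frame(k0 = k0[pairs], k1 = k1[pairs], k2 = k2[pairs]),
         n_markers = Ntot[pairs])
}

#' Maximum-likelihood IBD estimation by EM
#'
#' Maximizes `L(k0, k1, k2) = prod_s sum_d k_d P(g_i, g_j | IBD = d, p_s)`
#' over the 2-simplex for each non-inbred pair by EM from the uniform start
#' (1/3, 1/3, 1/3). The update replaces `k_d` with the mean posterior
#' probability of IBD state d across markers, which never decreases the
#' log-likelihood; iteration stops when the gain drops below `tol` or at
#' `max_iter`. `phi = k1/4 + k2/2`. Markers monomorphic at the plug-in
#' frequencies are excluded.
#'
#' @param g a [genotype_matrix()]
#' @param freqs optional alternate-allele frequencies (default: sample)
#' @param pairs optional 2-column index matrix; default all pairs
#' @param tol log-likelihood convergence tolerance
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate
#' @return kinship data frame with `k0`, `k1`, `k2`, `loglik`, `n_iter`
#' @export
mle_ibd_em <- function(g, freqs = NULL, pairs = NULL, tol = 1e-6,
                       max_iter = 1000) {
  dos <- g$dosage
  n <- nrow(dos)
  p <- freqs %||% (colMeans(dos, na.rm = TRUE) / 2)
  use <- which(is.finite(p) & p > 0 & p < 1)
  if (is.null(pairs)) pairs <- all_pairs(n)
  G <- dos[, use, drop = FALSE]
  storage.mode(G) <- "integer"
  res <- em_ibd_cpp(G, p[use], pairs, tol, as.integer(max_iter))
  nc <- sum(res[, "converged"] == 0)
  if (nc > 0)
    warning(nc, " pair(s) hit max_iter = ", max_iter, " before converging")
  kin_df(g, pairs, res[, "k1"] / 4 + res[, "k2"] / 2, "mle",
         extra = data.frame(k0 = res[, "k0"], k1 = res[, "k1"],
                            k2 = res[, "k2"], loglik = res[, "loglik"],
                            n_iter = res[, "n_iter"]),
         n_markers = res[, "n_markers"])
}

#' Weighted cross-chromosome aggregation of kinship estimates
#'
#' Combines per-chromosome kinship tables for the same pair set by a
#' weighted mean with weights equal to per-chromosome marker counts;
#' negative aggregated estimates are set to zero (clamping applied after
#' aggregation by default, or per chromosome with `clamp_each`).
#'
#' @param components list of kinship data frames (same pairs, same order)
#' @param clamp_each clamp negative per-chromosome values before averaging
#' @return aggregated kinship data frame
#' @export
aggregate_chromosomes <- function(components, clamp_each = FALSE) {
  stopifnot(length(components) >= 1)
  base <- components[[1]]
  num <- rep(0, nrow(base)); den <- rep(0, nrow(base))
  for (comp in components) {
    stopifnot(nrow(comp) == nrow(base),
              all(comp$id1 == base$id1), all(comp$id2 == base$id2))
    k <- comp$kinship
    if (clamp_each) k <- pmax(k, 0)
    num <- num + k * comp$n_markers
    den <- den + comp$n_markers
  }
  if (any(den == 0)) stop("zero total marker weight for some pair(s)")
  out <- base
  out$kinship <- pmax(num / den, 0)
  out$n_markers <- den
  out
}

#' Write a kinship table as long-format TSV
#' @param kin kinship data frame
#' @param path file path
#' @param design optional design label column to add
#' @return `path`, invisibly
#' @export
write_kinship <- function(kin, path, design = NA_character_) {
  kin$design <- design
  write.table(kin[, c("id1", "id2", "estimator", "design", "n_markers", "kinship")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
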