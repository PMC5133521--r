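# Independent reference implementations used as oracles in tests.
# These deliberately use naive double loops / enumeration, not the package's
# vectorized or compiled code paths.

# tiny genotype matrix from a dosage matrix (one chromosome, 1 Mb spacing)
toy_geno <- function(dos, chrom = "1") {
  S <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("S", seq_len(nrow(dos)))
  v <- data.frame(id = paste0("v", seq_len(S)), chrom = chrom,
                  bp = seq_len(S) * 1e6, cM = seq_len(S),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  storage.mode(dos) <- "integer"
  genotype_matrix(dos, v)
}

# per-marker likelihoods P(gi, gj | IBD = d, p) for a non-inbred pair,
# enumerated from the conditional genotype-pair distribution
ref_pair_lik <- function(gi, gj, p) {
  S <- length(p)
  out <- matrix(NA_real_, S, 3)
  for (s in seq_len(S)) {
    ps <- p[s]; qs <- 1 - ps
    gp <- c(qs^2, 2 * ps * qs, ps^2)
    t1 <- matrix(0, 3, 3)
    t1[1, 1] <- qs^3; t1[3, 3] <- ps^3
    t1[1, 2] <- t1[2, 1] <- ps * qs^2
    t1[3, 2] <- t1[2, 3] <- ps^2 * qs
    t1[2, 2] <- ps * qs
    a <- gi[s] + 1L; b <- gj[s] + 1L
    out[s, ] <- c(gp[a] * gp[b], t1[a, b], if (a == b) gp[a] else 0)
  }
  out
}

ref_loglik <- function(k, lik) sum(log(lik %*% k))

# reference EM returning the full log-likelihood trace
ref_em <- function(gi, gj, p, tol = 1e-6, max_iter = 1000) {
  lik <- ref_pair_lik(gi, gj, p)
  k <- rep(1 / 3, 3)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- sweep(lik, 2, k, "*")
    tot <- rowSums(w)
    trace <- c(trace, sum(log(tot)))
    k <- colMeans(w / tot)
    if (it > 1 && diff(tail(trace, 2)) < tol) break
  }
  list(k = k, trace = trace)
}

# exhaustive grid search over the 2-simplex at the given resolution
grid_mle <- function(gi, gj, p, res = 0.01) {
  lik <- ref_pair_lik(gi, gj, p)
  best <- NULL; best_ll <- -Inf
  for (k0 in seq(0, 1, by = res)) {
    for (k1 in seq(0, 1 - k0, by = res)) {
      ll <- ref_loglik(c(k0, k1, 1 - k0 - k1), lik)
      if (ll > best_ll) { best_ll <- ll; best <- c(k0, k1, 1 - k0 - k1) }
    }
  }
  list(k = best, loglik = best_ll)
}

# double-loop evaluation of the ratio-of-sums GRM formula
brute_grm <- function(dos) {
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- f > 0.5
  dos[, flip] <- 2 - dos[, flip]
  p <- pmin(f, 1 - f)
  use <- p > 0
  dos <- dos[, use, drop = FALSE]; p <- p[use]
  n <- nrow(dos)
  psi <- matrix(0, n, n)
  den <- sum(2 * p * (1 - p))
  for (i in 1:n) for (j in 1:n) {
    num <- 0
    for (s in seq_along(p)) {
      gi <- dos[i, s]; gj <- dos[j, s]
      if (is.na(gi)) gi <- 2 * p[s]
      if (is.na(gj)) gj <- 2 * p[s]
      num <- num + (gi - 2 * p[s]) * (gj - 2 * p[s])
    }
    psi[i, j] <- num / den
  }
  psi
}

# all-pairs greedy LD pruning with the same drop-the-later-variant rule,
# unlimited window
brute_prune <- function(dos, r2_max) {
  v <- apply(dos, 2, var, na.rm = TRUE)
  cand <- which(!is.na(v) & v > 0)
  kept <- integer(0)
  for (j in cand) {
    ok <- TRUE
    for (i in kept) {
      r <- suppressWarnings(cor(dos[, i], dos[, j], use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

# direct REML log-likelihood of y = Xb + g + e at variance ratio h2,
# computed from the full multivariate normal density (no rotation tricks)
ref_reml_ll <- function(h2, y, Xd, K) {
  n <- length(y); p <- ncol(Xd)
  V <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V)
  b <- solve(t(Xd) %*% Vi %*% Xd, t(Xd) %*% Vi %*% y)
  r <- y - Xd %*% b
  s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * s2) + determinant(V)$modulus +
             determinant(t(Xd) %*% Vi %*% Xd, logarithm = TRUE)$modulus + (n - p)))
}

# quick unlinked founder population (no pedigrees): n unrelated samples
# with admixture proportions q (n x K) and per-pop alt freqs (K x S)
sim_unrelated <- function(q, freq, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(q); S <- ncol(freq); K <- nrow(freq)
    dos <- matrix(0L, n, S)
    for (h in 1:2) {
      pops <- matrix(0L, n, S)
      for (i in 1:n) pops[i, ] <- sample.int(K, S, TRUE, prob = q[i, ])
      dos <- dos + matrix(rbinom(n * S, 1L, freq[cbind(as.vector(pops),
                                                       rep(seq_len(S), each = n))]),
                          n, S)
    }
    storage.mode(dos) <- "integer"
    toy_geno(dos)
  })
}
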