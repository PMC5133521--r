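#' Fit the null linear mixed model (variance-component estimation)
#'
#' Model: `y = X beta + g + e` with `g ~ N(0, sigma_g2 * K)` and
#' `e ~ N(0, sigma_e2 * I)`. After one eigendecomposition of `K`, the REML
#' (default) or ML criterion is optimized in one dimension over the
#' heritability ratio `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`; fixed
#' effects come from generalized least squares at the optimum. Tiny
#' negative eigenvalues of empirical matrices (> -1e-8 relative) are
#' clipped to zero.
#'
#' @param y response vector
#' @param X covariate matrix (an intercept column is added if absent);
#'   `NULL` for intercept-only
#' @param K covariance-structure matrix, e.g. `2 * Phi` or a GRM
#' @param method `"REML"` (default) or `"ML"`
#' @param eig optional precomputed `eigen(K, symmetric = TRUE)` to reuse
#'   across fits on the same samples
#' @return object of class `null_lmm`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `beta`, `loglik`, `boundary` flag, rotation cache
#' @export
fit_null_lmm <- function(y, X = NULL, K, method = c("REML", "ML"), eig = NULL) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1) else {
    X <- as.matrix(X)
    if (!any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0)))
      X <- cbind(1, X)
  }
  p <- ncol(X)
  if (n < p + 2) stop("need at least ncol(X) + 2 samples")
  if (is.null(eig)) {
    if (max(abs(K - t(K))) > 1e-6) stop("K must be symmetric")
    eig <- eigen(K, symmetric = TRUE)
  }
  lam <- eig$values
  if (min(lam) < -1e-8 * max(abs(lam)))
    stop("K is not positive semidefinite; clip its negative eigenvalues first")
  lam <- pmax(lam, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  crit <- function(h2) {
    w <- h2 * lam + (1 - h2)
    wi <- 1 / w
    XtW <- Xt * wi
    XtWX <- crossprod(Xt, XtW)
    b <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 * wi)
    if (method == "REML") {
      df <- n - p
      s2 <- rss / df
      -0.5 * (df * log(2 * pi * s2) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus + df)
    } else {
      s2 <- rss / n
      -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    }
  }
  opt <- optimize(crit, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  # guard the zero boundary explicitly (optimize() never samples endpoints)
  # and prefer it when the criterion is flat there, so unidentifiable
  # variance splits (e.g. K proportional to I) report sigma_g2 = 0
  ll0 <- crit(1e-10)
  if (ll0 >= opt$objective - 1e-8) {
    h2 <- 1e-10; ll <- ll0
  } else {
    h2 <- opt$maximum; ll <- opt$objective
  }
  w <- h2 * lam + (1 - h2)
  wi <- 1 / w
  XtW <- Xt * wi
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  s2 <- sum(r^2 * wi) / (if (method == "REML") n - p else n)
  boundary <- h2 < 1e-4
  structure(list(sigma_g2 = if (boundary) 0 else s2 * h2,
                 sigma_e2 = s2 * (1 - h2),
                 h2 = if (boundary) 0 else h2,
                 beta = drop(beta), loglik = ll, method = method,
                 boundary = boundary,
                 U = U, lambda = lam, yt = drop(yt), Xt = Xt,
                 w = drop(w) * s2, n = n),
            class = "null_lmm")
}

#' Narrow-sense heritability from a null model fit
#' @param null a `null_lmm`
#' @return `sigma_g2 / (sigma_g2 + sigma_e2)`
#' @export
h2_of <- function(null) null$sigma_g2 / (null$sigma_g2 + null$sigma_e2)

#' Mixed-model association scan with fixed variance components
#'
#' For every predictor column (SNP dosage or ancestry dosage), a
#' generalized-least-squares Wald test of its coefficient with the
#' covariance fixed at the null-model estimates (the EMMAX approximation:
#' variance components are estimated once, not per marker). Two-sided
#' p-values from the large-sample normal. Predictors collinear with the
#' covariates (including constant columns) are flagged and get missing
#' p-values. Underflowing p-values are floored at the smallest positive
#' normal double and flagged in the `floored` column.
#'
#' @param null a `null_lmm` from [fit_null_lmm()]
#' @param D predictor matrix (samples x predictors) or a single vector
#' @param names optional predictor names
#' @return data frame: `predictor`, `beta`, `se`, `stat`, `p`, `collinear`,
#'   `floored`
#' @export
emmax_scan <- function(null, D, names = NULL) {
  if (is.null(dim(D))) D <- matrix(D, ncol = 1)
  Dt <- crossprod(null$U, D)
  sw <- 1 / sqrt(null$w)
  ys <- null$yt * sw
  Xs <- null$Xt * sw
  Ds <- Dt * sw
  qx <- qr(Xs)
  yr <- qr.resid(qx, ys)
  Dr <- qr.resid(qx, Ds)
  dd <- colSums(Dr^2)
  scale <- colSums(Ds^2)
  collinear <- dd <= 1e-10 * pmax(scale, 1)
  beta <- colSums(Dr * yr) / dd
  se <- 1 / sqrt(dd)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  floored <- is.finite(p) & p < .Machine$double.xmin
  p[floored] <- .Machine$double.xmin
  beta[collinear] <- NA; se[collinear] <- NA; z[collinear] <- NA; p[collinear] <- NA
  data.frame(predictor = names %||% colnames(D) %||% paste0("V", seq_len(ncol(D))),
             beta = beta, se = se, stat = z, p = p,
             collinear = collinear, floored = floored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname emmax_scan
#' @param d a single predictor vector
#' @export
test_dosage <- function(null, d) emmax_scan(null, matrix(d, ncol = 1))

#' Admixture mapping on local-ancestry dosage
#'
#' One mixed-model scan per named ancestral population: at each locus the
#' predictor is the number of haplotypes (0/1/2) the sample inherits from
#' that population. The null model's relatedness matrix should come from
#' the PC-adjusted estimator so global ancestry proportions are absorbed.
#' Monomorphic loci (all samples identical) are skipped.
#'
#' @param null a `null_lmm`
#' @param la a [local_ancestry()]
#' @param population population label to scan
#' @param loci optional variant indices to test (default: all variants)
#' @return scan data frame with locus metadata columns prepended
#' @export
admixture_map <- function(null, la, population, loci = NULL) {
  D <- ancestry_dosage(la, population)
  loci <- loci %||% seq_len(ncol(D))
  D <- D[, loci, drop = FALSE]
  res <- emmax_scan(null, D, names = colnames(D) %||% paste0("locus", loci))
  res$locus <- loci
  res$population <- population
  res$skipped <- res$collinear
  res
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi^2_1 statistics) / 0.4549364` (the median of a
#' 1-df chi-squared). P-values are converted through the inverse chi^2_1
#' quantile.
#'
#' @param p p-values (two-sided), or
#' @param chisq 1-df chi-squared statistics (used if `p` is `NULL`)
#' @return lambda
#' @export
genomic_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p) || length(p) == 0) stop("no statistics supplied")
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chisq) == 0) stop("no statistics supplied")
  median(chisq, na.rm = TRUE) / qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Significance thresholds for the two mapping strategies
#'
#' `"bonferroni"`: `alpha / n_tests` for the SNP-dosage association scan.
#' `"admixture"`: twice the genome-wide nominal pointwise value `p0`
#' (one scan per two compared ancestral populations), i.e. `2 * p0`.
#'
#' @param n_tests number of tests (bonferroni mode)
#' @param mode `"bonferroni"` or `"admixture"`
#' @param alpha family-wise error rate (bonferroni)
#' @param p0 nominal pointwise genome-wide p-value (admixture)
#' @return the significance threshold
#' @export
significance_threshold <- function(n_tests = NULL,
                                   mode = c("bonferroni", "admixture"),
                                   alpha = 0.05, p0 = 7e-6) {
  mode <- match.arg(mode)
  if (mode == "bonferroni") {
    if (is.null(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    alpha / n_tests
  } else {
    2 * p0
  }
}
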