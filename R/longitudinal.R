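spline_basis <- function(age, n_knots = 2, boundary = NULL) {
  if (n_knots < 0) stop("n_knots must be >= 0")
  boundary <- boundary %||% quantile(age, c(0.05, 0.95), names = FALSE)
  knots <- if (n_knots > 0)
    quantile(age, seq_len(n_knots) / (n_knots + 1), names = FALSE) else NULL
  # boundary knots sit at inner percentiles by design, so bs() sees values
  # outside them; its ill-conditioning warning is expected and harmless here
  B <- suppressWarnings(splines::bs(age, knots = knots, degree = 3,
                                    Boundary.knots = boundary))
  attr(B, "spec") <- list(knots = knots, boundary = boundary)
  B
}

#' Adjust a longitudinal trait for fixed effects
#'
#' Least-squares fit of the trait on medication, smoking, sex, and
#' smoking- and sex-specific cubic-spline curves for age; the residuals
#' are the adjusted trait. Rows with incomplete covariates are dropped
#' with a message.
#'
#' @param pheno long-format phenotype table (`sample`, `visit`, `age`,
#'   `trait`, `med`, `smoke`, `sex`)
#' @param n_knots internal knots of the age spline (default 2; boundary
#'   knots at the 5th/95th age percentiles)
#' @return list of class `trait_adjustment`: `coefficients`, `pheno`
#'   (input rows kept, with an `adj_trait` column), `design`
#' @export
adjust_trait <- function(pheno, n_knots = 2) {
  need <- c("sample", "visit", "age", "trait", "med", "smoke", "sex")
  stopifnot(all(need %in% names(pheno)))
  cc <- complete.cases(pheno[, need])
  if (!all(cc)) message("dropping ", sum(!cc), " rows with incomplete covariates")
  ph <- pheno[cc, , drop = FALSE]
  B <- spline_basis(ph$age, n_knots)
  X <- cbind(`(Intercept)` = 1, med = ph$med, smoke = ph$smoke, sex = ph$sex,
             B, B * ph$smoke, B * ph$sex)
  colnames(X) <- c("(Intercept)", "med", "smoke", "sex",
                   paste0("age", seq_len(ncol(B))),
                   paste0("smoke:age", seq_len(ncol(B))),
                   paste0("sex:age", seq_len(ncol(B))))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient adjustment design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  coefs <- qr.coef(qx, ph$trait)
  ph$adj_trait <- drop(qr.resid(qx, ph$trait))
  structure(list(coefficients = coefs, pheno = ph, design = X,
                 spline = attr(B, "spec")),
            class = "trait_adjustment")
}

# observation-level negative log-likelihood of the variance-curve model,
# with fixed effects profiled out by GLS
varcurve_nll <- function(theta, Bg, Be, A, X, y) {
  k <- ncol(Bg)
  sg <- exp(0.5 * drop(Bg %*% theta[seq_len(k)]))          # sigma_g(age)
  ve <- exp(drop(Be %*% theta[k + seq_len(ncol(Be))]))      # sigma_e^2(age)
  V <- A * tcrossprod(sg)
  diag(V) <- diag(V) + ve
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  0.5 * (logdet + sum(r * Vi_r) + length(y) * log(2 * pi))
}

#' Age-varying additive and environmental variance curves
#'
#' Gaussian likelihood of the longitudinal model
#' `y_it = x_it beta + sigma_g(age_it) u_i + e_it` with `u ~ N(0, 2 Phi)`
#' and `e_it ~ N(0, sigma_e2(age_it))`, so
#' `Cov(y_it, y_jt') = 2 Phi_ij sigma_g(age_it) sigma_g(age_jt') +
#' 1[i=j, t=t'] sigma_e2(age_it)`. Both `log sigma_g2(.)` and
#' `log sigma_e2(.)` are cubic splines in age (log scale for both
#' guarantees positivity). Spline coefficients are optimized numerically
#' with fixed effects profiled by GLS and seeded random restarts;
#' `h2(age) = sigma_g2(age) / (sigma_g2(age) + sigma_e2(age))` pointwise,
#' with 95 % bands by parametric bootstrap.
#'
#' @param pheno phenotype table with an `adj_trait` column (from
#'   [adjust_trait()]) or a `trait_adjustment`
#' @param Phi pedigree (or estimated) kinship matrix over subjects
#' @param n_knots internal spline knots (0 = constant variances)
#' @param covariates observation-level fixed-effect matrix (default:
#'   intercept only, appropriate for a pre-adjusted trait)
#' @param n_restarts random optimizer restarts (best likelihood kept)
#' @param n_boot parametric-bootstrap replicates for the 95 % band
#'   (0 disables the band)
#' @param age_grid ages at which to report the heritability curve
#' @param seed integer seed for restarts and bootstrap
#' @return object of class `variance_curves`: spline coefficients,
#'   `loglik`, convergence info, and `curve` (data frame: `age`, `sigma_g2`,
#'   `sigma_e2`, `h2`, and bootstrap `lower`/`upper` when requested)
#' @export
fit_variance_curves <- function(pheno, Phi, n_knots = 2, covariates = NULL,
                                n_restarts = 3, n_boot = 0, age_grid = NULL,
                                seed = NULL) {
  if (inherits(pheno, "trait_adjustment")) pheno <- pheno$pheno
  stopifnot("adj_trait" %in% names(pheno))
  ids <- unique(pheno$sample)
  si <- match(pheno$sample, ids)
  Phi <- Phi[ids, ids]
  A <- 2 * Phi[si, si]                    # observation-level additive structure
  y <- pheno$adj_trait
  age <- pheno$age
  nobs <- length(y)
  X <- covariates %||% matrix(1, nobs, 1)
  if (n_knots > 0) {
    Bg <- cbind(1, spline_basis(age, n_knots))
  } else {
    Bg <- matrix(1, nobs, 1)
  }
  Be <- Bg
  npar <- ncol(Bg) + ncol(Be)
  if (nobs <= npar + ncol(X)) stop("fewer observations than parameters")
  v0 <- var(y)
  start0 <- c(log(0.4 * v0), rep(0, ncol(Bg) - 1),
              log(0.6 * v0), rep(0, ncol(Be) - 1))
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1, n_restarts))) {
      st <- if (r == 1) start0 else start0 + rnorm(npar, 0, 0.5)
      fit <- tryCatch(
        optim(st, varcurve_nll, Bg = Bg, Be = Be, A = A, X = X, y = y,
              method = "BFGS",
              control = list(maxit = 300, reltol = 1e-10)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("variance-curve optimization failed")
    if (best$convergence != 0)
      warning("optimizer did not fully converge (code ", best$convergence,
              "); returning last iterate")
    theta <- best$par
    age_grid <- age_grid %||% seq(min(age), max(age), length.out = 25)
    curve_of <- function(theta) {
      Bgg <- if (n_knots > 0)
        cbind(1, predict_basis(Bg, age, age_grid, n_knots)) else
        matrix(1, length(age_grid), 1)
      sg2 <- exp(drop(Bgg %*% theta[seq_len(ncol(Bg))]))
      se2 <- exp(drop(Bgg %*% theta[ncol(Bg) + seq_len(ncol(Be))]))
      data.frame(age = age_grid, sigma_g2 = sg2, sigma_e2 = se2,
                 h2 = sg2 / (sg2 + se2))
    }
    curve <- curve_of(theta)
    if (n_boot > 0) {
      k <- ncol(Bg)
      sg <- exp(0.5 * drop(Bg %*% theta[seq_len(k)]))
      ve <- exp(drop(Be %*% theta[k + seq_len(ncol(Be))]))
      V <- A * tcrossprod(sg); diag(V) <- diag(V) + ve
      ch <- chol(V)
      # beta from the fit (profiled)
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
      beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
      mu <- drop(X %*% beta)
      H <- matrix(NA_real_, n_boot, length(age_grid))
      for (b in seq_len(n_boot)) {
        yb <- mu + drop(crossprod(ch, rnorm(nobs)))
        fb <- tryCatch(
          optim(theta, varcurve_nll, Bg = Bg, Be = Be, A = A, X = X, y = yb,
                method = "BFGS", control = list(maxit = 200)),
          error = function(e) NULL)
        if (!is.null(fb)) H[b, ] <- curve_of(fb$par)$h2
      }
      curve$lower <- apply(H, 2, quantile, 0.025, na.rm = TRUE)
      curve$upper <- apply(H, 2, quantile, 0.975, na.rm = TRUE)
    }
    structure(list(theta = theta, loglik = -best$value,
                   convergence = best$convergence, n_knots = n_knots,
                   curve = curve, Bg_cols = ncol(Bg)),
              class = "variance_curves")
  })
}

# rebuild the age-spline basis at new ages with the training knots;
# evaluation ages are clamped to the boundary knots
predict_basis <- function(B_train, age_train, age_new, n_knots) {
  boundary <- quantile(age_train, c(0.05, 0.95), names = FALSE)
  knots <- if (n_knots > 0)
    quantile(age_train, seq_len(n_knots) / (n_knots + 1), names = FALSE) else NULL
  age_clamped <- pmin(pmax(age_new, boundary[1]), boundary[2])
  splines::bs(age_clamped, knots = knots, degree = 3, Boundary.knots = boundary)
}

#' Per-visit (cross-sectional) heritability
#'
#' Restricts the adjusted trait to one visit and returns
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)` from the null mixed model with
#' covariance structure `2 * Phi`.
#'
#' @param pheno phenotype table with `adj_trait` (or a `trait_adjustment`)
#' @param Phi kinship matrix over subjects
#' @param visit visit number to analyze
#' @param eig optional precomputed eigendecomposition of `2 * Phi` for the
#'   visit's subjects (in their row order)
#' @return list: `h2`, `sigma_g2`, `sigma_e2`, the underlying `null_lmm`
#' @export
per_visit_heritability <- function(pheno, Phi, visit = 1, eig = NULL) {
  if (inherits(pheno, "trait_adjustment")) pheno <- pheno$pheno
  ph <- pheno[pheno$visit == visit, ]
  if (anyDuplicated(ph$sample)) stop("multiple observations per subject at this visit")
  K <- 2 * Phi[ph$sample, ph$sample]
  fit <- fit_null_lmm(ph$adj_trait, X = NULL, K = K, eig = eig)
  list(h2 = h2_of(fit), sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
       fit = fit)
}
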