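# Phylogenetic generalized least squares with Pagel's lambda.
#
# Model: y = b0 + b1 * x + e,  e ~ N(0, sigma^2 * V(lambda)), where
# V(lambda) is the Brownian-motion covariance of the species used with its
# off-diagonal entries scaled by lambda. lambda is estimated by maximizing
# the profile log-likelihood (sigma^2 and the coefficients profiled out in
# closed form); inference on the slope uses the t distribution with n - 2
# degrees of freedom and the unbiased variance estimate, the usual GLS
# t-test convention.

#' Generalized least squares fit of y on x under a known covariance
#'
#' Closed-form GLS of the simple regression `y ~ x` with error covariance
#' proportional to `V`. Estimates are computed by whitening with the
#' Cholesky factor of `V`. The reported log-likelihood uses the ML variance
#' (divisor n); the slope standard error uses the unbiased variance
#' (divisor n - 2).
#'
#' @param y,x Numeric vectors of equal length (n >= 3).
#' @param V Symmetric positive-definite covariance matrix (n x n), or a
#'   `phylo_vcv` object.
#' @return An object of class `pgls_fit` with elements n, intercept, slope,
#'   slope_se, t_stat, p_value, sigma2_hat, residuals, logLik, lambda_hat
#'   (`NA` here; set by [profile_lambda()]).
#' @export
gls_fit <- function(y, x, V) {
  if (inherits(V, "phylo_vcv")) V <- V$C
  n <- length(y)
  if (length(x) != n || nrow(V) != n || ncol(V) != n) {
    abort_config("y, x and V must agree in dimension")
  }
  if (n < 3L) abort_config("need at least 3 observations for GLS")
  if (max(x) - min(x) <= 0) abort_numeric("constant predictor: slope undefined")
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) abort_numeric("covariance matrix is singular or not positive definite")
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))
  # whiten: U' W = [X y]  =>  W = U'^-1 [X y]
  W <- backsolve(U, cbind(X, y), transpose = TRUE)
  Xw <- W[, 1:2, drop = FALSE]
  yw <- W[, 3L]
  qr_x <- qr(Xw)
  if (qr_x$rank < 2L) abort_numeric("design matrix rank-deficient after whitening")
  beta <- qr.coef(qr_x, yw)
  rw <- yw - Xw %*% beta
  rss_w <- sum(rw^2)                       # r' V^-1 r
  resid <- as.numeric(y - X %*% beta)
  names(resid) <- rownames(V)
  sigma2_unb <- rss_w / (n - 2)
  XtViX_inv <- chol2inv(qr.R(qr_x))        # (X' V^-1 X)^-1
  slope_se <- sqrt(sigma2_unb * XtViX_inv[2L, 2L])
  t_stat <- beta[2L] / slope_se
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  sigma2_ml <- rss_w / n
  logdetV <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  structure(list(
    n = n, intercept = unname(beta[1L]), slope = unname(beta[2L]),
    slope_se = slope_se, t_stat = unname(t_stat), p_value = unname(p),
    sigma2_hat = sigma2_unb, residuals = resid, logLik = ll,
    lambda_hat = NA_real_
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS fit: n = %d, slope = %.4g (SE %.3g), t = %.3g, p = %.3g\n",
    x$n, x$slope, x$slope_se, x$t_stat, x$p_value))
  if (!is.na(x$lambda_hat)) {
    cat(sprintf("  lambda = %.4f, logLik = %.4f\n", x$lambda_hat, x$logLik))
  }
  invisible(x)
}

#' Profile maximum-likelihood estimation of Pagel's lambda
#'
#' Maximizes the GLS profile log-likelihood over `lambda` in `[0, 1]` by a
#' coarse grid (step 0.05) followed by bounded scalar refinement
#' ([stats::optimize()], tolerance 1e-6) around the best grid point; the
#' two-stage search guards against the multi-modality the profile can show
#' near the boundaries. Returns the full GLS fit at the maximizer.
#'
#' @param y,x Numeric vectors (species-aligned with `C$species`).
#' @param C A `phylo_vcv` covariance for exactly the species used.
#' @return A `pgls_fit` with `lambda_hat` and `logLik` set.
#' @export
profile_lambda <- function(y, x, C) {
  if (!inherits(C, "phylo_vcv")) abort_config("C must be a phylo_vcv object")
  ll_at <- function(lam) gls_fit(y, x, lambda_transform(C, lam))$logLik
  grid <- seq(0, 1, by = 0.05)
  ll_grid <- vapply(grid, ll_at, numeric(1))
  g <- which.max(ll_grid)
  lo <- grid[max(1L, g - 1L)]
  hi <- grid[min(length(grid), g + 1L)]
  lam_hat <- grid[g]
  ll_hat <- ll_grid[g]
  if (hi > lo) {
    opt <- stats::optimize(ll_at, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (is.finite(opt$objective) && opt$objective >= ll_hat) {
      lam_hat <- opt$maximum
      ll_hat <- opt$objective
    }
  }
  # snap to a boundary when the refinement lands within tolerance of it
  if (lam_hat < 1e-6) lam_hat <- 0
  if (lam_hat > 1 - 1e-6) lam_hat <- 1
  fit <- gls_fit(y, x, lambda_transform(C, lam_hat))
  fit$lambda_hat <- lam_hat
  fit
}

#' PGLS of a gene's root-to-tip omega on a phenotype
#'
#' Regresses `log10_omega_bar` on `log10(phenotype)` across the species
#' where both are defined, with the phylogenetic covariance rebuilt on
#' exactly those species and lambda estimated by maximum likelihood (or
#' fixed via `lambda`). Genes with fewer than `min_species` usable species
#' are skipped (returns `NULL` with an attribute carrying the reason is not
#' needed; callers test for `NULL`).
#'
#' @param rtt_gene Root-to-tip rows for one gene: `data.frame` with
#'   `species` and `log10_omega_bar` (NA rows dropped).
#' @param phenotype Named numeric vector of raw phenotype values (> 0), one
#'   per species (e.g. body mass in g); log10 is applied internally.
#' @param tree A labeled `phylo` object containing all used species.
#' @param min_species Minimum complete-case species to attempt the fit.
#' @param lambda Optional fixed lambda in `[0, 1]`; `NULL` (default)
#'   estimates it by ML.
#' @return A `pgls_fit` with an added `species` element, or `NULL` when too
#'   few species are usable.
#' @export
pgls_gene <- function(rtt_gene, phenotype, tree, min_species = 10, lambda = NULL) {
  ph <- phenotype[!is.na(phenotype) & phenotype > 0]
  rg <- rtt_gene[!is.na(rtt_gene$log10_omega_bar), , drop = FALSE]
  common <- intersect(rg$species, names(ph))
  common <- intersect(tree$tip.label, common)   # stable tree order
  if (length(common) < max(3L, min_species)) return(NULL)
  y <- rg$log10_omega_bar[match(common, rg$species)]
  x <- log10(ph[common])
  C <- vcv_matrix(tree, common)
  fit <- if (is.null(lambda)) {
    profile_lambda(y, x, C)
  } else {
    f <- gls_fit(y, x, lambda_transform(C, lambda))
    f$lambda_hat <- lambda
    f
  }
  fit$species <- common
  fit
}
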