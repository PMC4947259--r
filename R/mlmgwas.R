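# mean-imputed, samples x sites dosage matrix for kinship/PCA
.imputed_dosage <- function(x) {
  g <- t(x$calls)
  means <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx) > 0) g[idx] <- means[idx[, 2]]
  g
}

#' VanRaden genomic relationship matrix
#'
#' `K = W W' / (2 * sum(p_k (1 - p_k)))` where `W` is the
#' column-centered (by twice the allele frequency) dosage matrix, samples
#' by markers. Missing dosages are mean-imputed for this computation
#' only.
#'
#' @param x a `genotype_matrix`
#' @return symmetric n x n `kinship_matrix`
#' @export
vanraden_kinship <- function(x) {
  g <- .imputed_dosage(x)
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("kinship undefined: all sites monomorphic")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(g, 2, 2 * p)
  K <- tcrossprod(w) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(x$samples$sample_id, x$samples$sample_id)
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' Principal components of the genotype matrix
#'
#' PCA of the mean-imputed, centered dosage matrix (optionally scaled to
#' unit variance per site). Sign convention: within each component the
#' loading of largest magnitude is made positive, so results are
#' deterministic across platforms.
#'
#' @param x a `genotype_matrix`
#' @param k number of components, must be positive and below the sample
#'   count
#' @param standardize scale sites to unit variance before rotation
#' @return list with `scores` (n x k, rownames = sample ids),
#'   `variance_fractions` (length k) and `total_variance_fraction`
#' @export
genotype_pca <- function(x, k = 3, standardize = FALSE) {
  if (k <= 0) stop("k must be positive")
  if (k >= n_samples(x)) stop("k must be below the number of samples")
  g <- .imputed_dosage(x)
  v <- apply(g, 2, stats::var)
  g <- g[, v > 0, drop = FALSE]
  pc <- stats::prcomp(g, center = TRUE, scale. = standardize)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- x$samples$sample_id
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_fractions = fr[seq_len(k)],
       total_variance_fraction = sum(fr[seq_len(k)]))
}

#' Restricted maximum likelihood for a one-random-effect mixed model
#'
#' Fits `y = X b + u + e` with `var(u) = sigma2_g K`,
#' `var(e) = sigma2_e I` by profiling the REML log-likelihood over
#' `delta = sigma2_e / sigma2_g` on the spectrum of `K` projected off
#' `X` (eigendecomposition once, then 1-D optimisation of `log delta`
#' by golden-section/Brent). With `K = I` the two components are not
#' separately identifiable; only their sum is meaningful.
#'
#' @param y numeric response, length n
#' @param X fixed-effect design matrix (n x p, full column rank);
#'   `NULL` means intercept only
#' @param K n x n positive semidefinite kinship matrix
#' @param log_delta_range search interval for `log(delta)`
#' @return list with `sigma2_g`, `sigma2_e`, `delta`, `loglik`,
#'   `beta` (GLS fixed effects at the optimum), and the spectral pieces
#'   (`eigenvalues`, `eigenvectors` of K) reused by [mlm_scan()]
#' @export
reml_null <- function(y, X = NULL, K, log_delta_range = c(-12, 12)) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("X is rank deficient")
  stopifnot(nrow(X) == n, all(dim(K) == n))

  # spectrum of K restricted to the orthogonal complement of X
  qx <- qr.Q(qr(X))
  S_K_S <- K - qx %*% (crossprod(qx, K))
  S_K_S <- S_K_S - (S_K_S %*% qx) %*% t(qx)
  es <- eigen((S_K_S + t(S_K_S)) / 2, symmetric = TRUE)
  m <- n - p
  xi <- pmax(es$values[seq_len(m)], 0)
  eta <- as.numeric(crossprod(es$vectors[, seq_len(m), drop = FALSE], y))

  neg_restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- xi + delta
    ss <- sum(eta^2 / w)
    if (!is.finite(ss) || ss <= 0) return(1e10)
    0.5 * (m * log(ss) + sum(log(w)))
  }
  opt <- stats::optimize(neg_restricted_ll, interval = log_delta_range,
                         tol = 1e-8)
  # guard against boundary optima the interior search can miss
  for (b in log_delta_range) {
    if (neg_restricted_ll(b) < opt$objective) {
      opt <- list(minimum = b, objective = neg_restricted_ll(b))
    }
  }
  delta <- exp(opt$minimum)
  sigma2_g <- sum(eta^2 / (xi + delta)) / m
  sigma2_e <- delta * sigma2_g
  if (!is.finite(sigma2_g)) stop("REML likelihood is not finite")
  ll <- 0.5 * (m * (log(m / (2 * pi)) - 1 - log(sum(eta^2 / (xi + delta)))) -
                 sum(log(xi + delta)))

  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- sigma2_g * pmax(ek$values, 0) + sigma2_e
  Ut <- t(ek$vectors)
  ty <- Ut %*% y / sqrt(d)
  tX <- Ut %*% X / sqrt(d)
  beta <- qr.solve(tX, ty)
  list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = delta, loglik = ll,
       beta = as.numeric(beta), eigenvalues = pmax(ek$values, 0),
       eigenvectors = ek$vectors)
}

#' Mixed-linear-model association scan
#'
#' Per-marker generalized least squares under the covariance fixed at
#' the null-model REML optimum (the population-parameters-previously-
#' determined approximation): for each marker the effect, standard error
#' and Wald t-test are computed in the whitened coordinates
#' `V^{-1/2} = D^{-1/2} U'`. Markers below the MAF floor are skipped;
#' markers with missing calls are tested on the complete cases with the
#' same variance components (V restricted to those individuals).
#'
#' @param y numeric phenotype, length n, named by sample id or aligned
#'   with the matrix samples
#' @param X_covariates optional covariate matrix (e.g. PCA scores);
#'   an intercept is always added
#' @param K kinship matrix from [vanraden_kinship()]
#' @param x a `genotype_matrix`
#' @param maf_floor minimum MAF for a marker to be tested, default 0.05
#' @return an `mlm_result` data.frame with `scaffold`, `pos_bp`, `maf`,
#'   `beta`, `se`, `wald`, `p_value`; attributes `"sigma2_g"`,
#'   `"sigma2_e"`, `"delta"`, `"n_skipped"`
#' @export
mlm_scan <- function(y, X_covariates = NULL, K, x, maf_floor = 0.05) {
  n <- n_samples(x)
  stopifnot(length(y) == n)
  X <- cbind(Intercept = rep(1, n), X_covariates)
  fit <- reml_null(y, X, K)
  d <- fit$sigma2_g * fit$eigenvalues + fit$sigma2_e
  Tm <- t(fit$eigenvectors) / sqrt(d)  # V^{-1/2} up to rotation
  ty <- as.numeric(Tm %*% y)
  tX <- Tm %*% X
  V <- fit$sigma2_g * K + fit$sigma2_e * diag(n)

  maf <- site_maf(x)
  p_cov <- ncol(X)
  out <- data.frame(scaffold = x$sites$scaffold, pos_bp = x$sites$pos_bp,
                    maf = maf, beta = NA_real_, se = NA_real_,
                    wald = NA_real_, p_value = NA_real_)
  n_skipped <- 0L
  qrX <- qr(tX)
  for (i in seq_len(n_sites(x))) {
    g <- x$calls[i, ]
    if (is.na(maf[i]) || maf[i] < maf_floor) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (!anyNA(g)) {
      tg <- as.numeric(Tm %*% g)
      rg <- qr.resid(qrX, tg)
      ry <- qr.resid(qrX, ty)
      ssg <- sum(rg^2)
      if (ssg < 1e-12) { n_skipped <- n_skipped + 1L; next }
      beta <- sum(rg * ry) / ssg
      df <- n - p_cov - 1
      rss <- sum((ry - beta * rg)^2)
      se <- sqrt(rss / df / ssg)
      used_df <- df
    } else {
      ok <- which(!is.na(g))
      if (length(ok) <= p_cov + 1) { n_skipped <- n_skipped + 1L; next }
      Vs <- V[ok, ok]
      R <- chol(Vs)
      tys <- backsolve(R, y[ok], transpose = TRUE)
      tXs <- backsolve(R, cbind(X[ok, , drop = FALSE], g[ok]),
                       transpose = TRUE)
      qs <- qr(tXs[, -ncol(tXs), drop = FALSE])
      rg <- qr.resid(qs, tXs[, ncol(tXs)])
      ry <- qr.resid(qs, tys)
      ssg <- sum(rg^2)
      if (ssg < 1e-12) { n_skipped <- n_skipped + 1L; next }
      beta <- sum(rg * ry) / ssg
      df <- length(ok) - p_cov - 1
      rss <- sum((ry - beta * rg)^2)
      se <- sqrt(rss / df / ssg)
      used_df <- df
    }
    wald <- beta / se
    out$beta[i] <- beta
    out$se[i] <- se
    out$wald[i] <- wald
    out$p_value[i] <- 2 * stats::pt(-abs(wald), df = used_df)
  }
  attr(out, "sigma2_g") <- fit$sigma2_g
  attr(out, "sigma2_e") <- fit$sigma2_e
  attr(out, "delta") <- fit$delta
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("mlm_result", "data.frame")
  out
}

#' Multiple-testing thresholds for a genome-wide scan
#'
#' @param pvals per-marker p-values (NAs ignored for FDR flags)
#' @param m number of tests for the Bonferroni denominator; defaults to
#'   the number of non-missing p-values
#' @param alpha family-wise / FDR level, default 0.05
#' @return list with `bonferroni_cut` (`alpha / m`), `fdr_flags`
#'   (logical, BH q-value at most `alpha`) and `q_values`
#' @export
significance_thresholds <- function(pvals, m = NULL, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (is.null(m)) m <- sum(ok)
  if (m < 1) stop("m must be >= 1")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- bh_qvalues(pvals[ok])
  list(bonferroni_cut = alpha / m,
       fdr_flags = !is.na(q) & q <= alpha,
       q_values = q)
}

#' Quantile-quantile data for a p-value set
#'
#' @param pvals p-values in `(0, 1]`
#' @return data.frame with `expected` and `observed` -log10 quantiles
#'   (sorted ascending)
#' @export
qq_data <- function(pvals) {
  p <- sort(pvals[!is.na(pvals)])
  m <- length(p)
  if (m == 0) return(data.frame(expected = numeric(0), observed = numeric(0)))
  out <- data.frame(expected = rev(-log10((seq_len(m) - 0.5) / m)),
                    observed = rev(-log10(p)))
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' Median of the implied 1-df chi-square statistics over its null median
#' (0.4549); values near 1 indicate the structure correction is
#' calibrated.
#'
#' @param pvals p-values
#' @return lambda
#' @export
genomic_inflation <- function(pvals) {
  p <- pvals[!is.na(pvals)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
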