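#' Fit the linear mixed null model by REML
#'
#' Gaussian mixed model `y = X b + u + e`, `u ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`, fitted by the standard efficient trick: one
#' eigendecomposition of `K`, rotation of `y` and `X` onto the eigenbasis,
#' and one-dimensional REML optimization over the variance ratio
#' `delta = sigma_e^2 / sigma_g^2`. The ratio
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` is reported as SNP
#' heritability.
#'
#' @param y numeric response (transformed continuous trait).
#' @param X fixed-effect design matrix including the intercept (and
#'   typically stem-diameter and phase dummy covariates); must be full
#'   rank.
#' @param K a `kinship` object or symmetric PSD matrix conformable with `y`.
#' @param log_delta_range search interval for `log(delta)`.
#' @return object of class `lmm_null`: variance components, `h2` (the
#'   proportion of variance explained through `K`, using the average
#'   genetic variance `sigma_g^2 tr(K)/n` so the answer does not depend
#'   on the arbitrary scale of the relatedness matrix), fixed effects,
#'   REML log-likelihood, and rotated internals reused by
#'   [lmm_snp_test()].
#' @export
fit_lmm_null <- function(y, X, K, log_delta_range = c(-12, 12)) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 30L) stop("need at least 30 observations", call. = FALSE)
  if (nrow(X) != n) stop("X and y dimensions disagree", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("X is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  M <- if (inherits(K, "kinship")) K$K else as.matrix(K)
  if (max(abs(M - t(M))) > 1e-8) stop("K must be symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE)
  d <- ev$values
  if (min(d) < -1e-6 * max(abs(d)))
    stop("K is not positive semi-definite (most negative eigenvalue ",
         signif(min(d), 3), ")", call. = FALSE)
  d <- pmax(d, 0)
  U <- ev$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  p <- ncol(X)

  reml <- function(log_delta) {
    delta <- exp(log_delta)
    w <- d + delta
    sw <- 1 / sqrt(w)
    Xw <- Xr * sw
    yw <- yr * sw
    fit <- lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    # REML log-likelihood up to an additive constant
    -0.5 * ((n - p) * log(rss) + sum(log(w)) +
              determinant(crossprod(Xw), logarithm = TRUE)$modulus[1])
  }
  grid <- seq(log_delta_range[1], log_delta_range[2], length.out = 49L)
  vals <- vapply(grid, reml, numeric(1))
  i <- which.max(vals)
  opt <- optimize(reml, c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)]),
                  maximum = TRUE)
  # boundary-aware: compare interior optimum against the grid ends
  cand <- c(opt$maximum, grid[1], grid[length(grid)])
  best <- cand[which.max(vapply(cand, reml, numeric(1)))]
  delta <- exp(best)

  w <- d + delta
  sw <- 1 / sqrt(w)
  Xw <- Xr * sw
  yw <- yr * sw
  qrXw <- qr(Xw)
  beta <- qr.coef(qrXw, yw)
  rss <- sum(qr.resid(qrXw, yw)^2)
  sigma_g2 <- rss / (n - p)
  sigma_e2 <- sigma_g2 * delta
  # proportion of variance explained on the scale of this K: the average
  # per-sample genetic variance is sigma_g2 * tr(K)/n, so a GRM whose
  # diagonal is not 1 still yields an interpretable heritability
  kbar <- mean(d)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 * kbar / (sigma_g2 * kbar + sigma_e2),
                 beta = beta,
                 loglik_reml = reml(best), delta = delta, family = "gaussian",
                 n = n, p = p, U = U, d = d, sw = sw, yw = yw, qrXw = qrXw,
                 resid_w = qr.resid(qrXw, yw)),
            class = "lmm_null")
}

#' Single-SNP Wald test under the fitted mixed model
#'
#' Generalized least squares using the null model's variance components
#' (population-parameters-previously-estimated style): the SNP effect and
#' its standard error come from the weighted regression of the rotated
#' trait on the rotated dosage, after projecting out the covariates.
#' Missing dosages are mean-imputed; monomorphic SNPs are skipped.
#'
#' @param null an `lmm_null` from [fit_lmm_null()].
#' @param g dosage vector (0/1/2, `NA` allowed).
#' @return one-row data frame: `maf, beta, se, stat, p, test, note`.
#' @export
lmm_snp_test <- function(null, g) {
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (sd(g) == 0)
    return(data.frame(maf = NA_real_, beta = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, test = "lmm_wald",
                      note = "monomorphic", stringsAsFactors = FALSE))
  af <- mean(g) / 2
  gw <- drop(crossprod(null$U, g)) * null$sw
  gt <- qr.resid(null$qrXw, gw)
  yt <- null$resid_w
  gg <- sum(gt^2)
  beta <- sum(gt * yt) / gg
  df <- null$n - null$p - 1L
  s2 <- (sum(yt^2) - beta^2 * gg) / df
  se <- sqrt(s2 / gg)
  t <- beta / se
  data.frame(maf = min(af, 1 - af), beta = beta, se = se, stat = t,
             p = 2 * pt(-abs(t), df), test = "lmm_wald", note = "",
             stringsAsFactors = FALSE)
}

#' Genome scan with the mixed-model Wald test
#'
#' Vectorized [lmm_snp_test()] over all SNPs passing MAF and missingness
#' filters.
#'
#' @param null an `lmm_null` fit.
#' @param G a [genotype_matrix()] row-aligned with the null model's `y`.
#' @param maf_min,miss_max per-SNP filters.
#' @return association data frame: `snp_id, chrom, pos, maf, beta, se,
#'   stat, p, test` (filtered and monomorphic SNPs absent).
#' @export
lmm_gwas <- function(null, G, maf_min = 0.05, miss_max = 0.1) {
  maf <- snp_maf(G)
  missr <- colMeans(is.na(G$dosages))
  use <- which(!is.na(maf) & maf >= maf_min & missr <= miss_max &
                 !is_monomorphic(G))
  if (length(use) == 0L)
    return(empty_assoc("lmm_wald"))
  Z <- G$dosages[, use, drop = FALSE]
  storage.mode(Z) <- "double"
  mu <- colMeans(Z, na.rm = TRUE)
  for (j in seq_along(use)) {
    z <- Z[, j]; z[is.na(z)] <- mu[j]; Z[, j] <- z
  }
  Zw <- crossprod(null$U, Z) * null$sw
  Zt <- qr.resid(null$qrXw, Zw)
  yt <- null$resid_w
  gg <- colSums(Zt^2)
  beta <- colSums(Zt * yt) / gg
  df <- null$n - null$p - 1L
  s2 <- (sum(yt^2) - beta^2 * gg) / df
  se <- sqrt(s2 / gg)
  t <- beta / se
  data.frame(snp_id = G$snp_ids[use], chrom = G$chrom[use], pos = G$pos[use],
             maf = maf[use], beta = beta, se = se, stat = t,
             p = 2 * pt(-abs(t), df), test = "lmm_wald",
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_assoc <- function(test) {
  data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
             maf = numeric(0), beta = numeric(0), se = numeric(0),
             stat = numeric(0), p = numeric(0), test = character(0),
             stringsAsFactors = FALSE)
}

#' Genomic-control inflation factor
#'
#' Median association chi-square divided by the null median 0.455.
#'
#' @param p vector of p-values (two-sided, 1 df).
#' @return scalar lambda.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
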