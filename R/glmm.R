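#' Fit the logistic mixed null model by penalized quasi-likelihood
#'
#' Dichotomized (zero vs nonzero) traits are modelled as
#' `logit P(y=1) = X b + u`, `u ~ N(0, tau K)`. Fitting follows the
#' classic PQL scheme: from the current fit form the working response
#' `z = eta + (y - mu) / (mu (1 - mu))`, solve the heteroscedastic linear
#' mixed model for `z` (REML for `tau` by one-dimensional optimization),
#' and iterate until the fixed effects move less than `tol` (default
#' 1e-6) or `max_iter` (50) iterations.
#'
#' @param y_bin 0/1 response.
#' @param X fixed-effect design matrix including intercept; full rank.
#' @param K `kinship` object or PSD matrix.
#' @param fix_tau optional fixed value for the kinship variance component
#'   (`0` reduces the model to plain logistic regression).
#' @param max_iter,tol PQL iteration controls.
#' @return object of class `glmm_null`: `tau`, `beta`, fitted
#'   probabilities `mu`, the projection matrix `P` used by the score test,
#'   latent-scale heritability `h2` (`tau / (tau + pi^2/3)`), and a
#'   `converged` flag (non-converged fits are marked unusable).
#' @export
fit_glmm_null <- function(y_bin, X, K, fix_tau = NULL, max_iter = 50L,
                          tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y_bin)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient", call. = FALSE)
  M <- if (inherits(K, "kinship")) K$K else as.matrix(K)

  fit0 <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit0$coefficients
  eta <- drop(X %*% beta)
  tau <- if (is.null(fix_tau)) 0.1 else fix_tau
  converged <- FALSE

  working_reml <- function(log_tau, z, Wi) {
    tt <- exp(log_tau)
    V <- tt * M + diag(Wi, n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(-1e10)
    Vi_z <- backsolve(R, forwardsolve(t(R), z))
    Vi_X <- backsolve(R, forwardsolve(t(R), X))
    XtViX <- crossprod(X, Vi_X)
    b <- solve(XtViX, crossprod(Vi_X, z))
    r <- z - drop(X %*% b)
    Vi_r <- backsolve(R, forwardsolve(t(R), r))
    -0.5 * (2 * sum(log(diag(R))) +
              determinant(XtViX, logarithm = TRUE)$modulus[1] +
              sum(r * Vi_r))
  }

  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8))
      stop("separation: fitted probabilities pinned at 0/1; ",
           "reduce the covariate set", call. = FALSE)
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    Wi <- 1 / W
    if (is.null(fix_tau)) {
      opt <- optimize(working_reml, c(-10, 5), z = z, Wi = Wi, maximum = TRUE)
      tau <- exp(opt$maximum)
      if (working_reml(-20, z, Wi) >= opt$objective) tau <- 0
    }
    V <- tau * M + diag(Wi, n)
    R <- chol(V)
    Vi_X <- backsolve(R, forwardsolve(t(R), X))
    XtViX <- crossprod(X, Vi_X)
    beta_new <- drop(solve(XtViX, crossprod(Vi_X, z)))
    r <- z - drop(X %*% beta_new)
    Vi_r <- backsolve(R, forwardsolve(t(R), r))
    b_new <- tau * drop(M %*% Vi_r)
    eta <- drop(X %*% beta_new) + b_new
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }

  mu <- plogis(eta)
  W <- mu * (1 - mu)
  V <- tau * M + diag(1 / W, n)
  Vi <- chol2inv(chol(V))
  Vi_X <- Vi %*% X
  P <- Vi - Vi_X %*% solve(crossprod(X, Vi_X), t(Vi_X))
  structure(list(tau = tau, beta = beta, mu = mu, eta = eta,
                 h2 = tau / (tau + pi^2 / 3), family = "binomial",
                 P = P, XtViX = crossprod(X, Vi_X), y = y, X = X,
                 n = n, p = ncol(X), converged = converged,
                 iterations = it),
            class = "glmm_null")
}

#' Score test for one SNP under the logistic mixed model
#'
#' `U = g'(y - mu)` with variance `g' P g` from the null-model projection;
#' the squared standardized score is referred to chi-square with 1 df.
#'
#' @param null a `glmm_null` fit.
#' @param g dosage vector (0/1/2, `NA` mean-imputed).
#' @return one-row data frame `maf, beta, se, stat, p, test, note` (`beta`
#'   is `NA`: the score test does not estimate an effect).
#' @export
glmm_score_test <- function(null, g) {
  if (!null$converged)
    stop("null model did not converge; results would be unusable", call. = FALSE)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (sd(g) == 0)
    return(data.frame(maf = NA_real_, beta = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, test = "glmm_score",
                      note = "monomorphic", stringsAsFactors = FALSE))
  af <- mean(g) / 2
  U <- sum(g * (null$y - null$mu))
  v <- drop(crossprod(g, null$P %*% g))
  stat <- if (v <= 0) 0 else U^2 / v
  p <- if (v <= 0) 1 else pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(maf = min(af, 1 - af), beta = NA_real_, se = NA_real_,
             stat = stat, p = p, test = "glmm_score", note = "",
             stringsAsFactors = FALSE)
}

#' Genome scan with the logistic mixed-model score test
#'
#' @param null a `glmm_null` fit.
#' @param G a [genotype_matrix()] row-aligned with the null model.
#' @param maf_min,miss_max per-SNP filters.
#' @return association data frame (same columns as [lmm_gwas()]).
#' @export
glmm_gwas <- function(null, G, maf_min = 0.05, miss_max = 0.1) {
  if (!null$converged)
    stop("null model did not converge; results would be unusable", call. = FALSE)
  maf <- snp_maf(G)
  missr <- colMeans(is.na(G$dosages))
  use <- which(!is.na(maf) & maf >= maf_min & missr <= miss_max &
                 !is_monomorphic(G))
  if (length(use) == 0L) return(empty_assoc("glmm_score"))
  Z <- G$dosages[, use, drop = FALSE]
  storage.mode(Z) <- "double"
  mu_z <- colMeans(Z, na.rm = TRUE)
  for (j in seq_along(use)) {
    z <- Z[, j]; z[is.na(z)] <- mu_z[j]; Z[, j] <- z
  }
  U <- drop(crossprod(Z, null$y - null$mu))
  v <- colSums(Z * (null$P %*% Z))
  stat <- ifelse(v <= 0, 0, U^2 / v)
  p <- ifelse(v <= 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  data.frame(snp_id = G$snp_ids[use], chrom = G$chrom[use], pos = G$pos[use],
             maf = maf[use], beta = NA_real_, se = NA_real_, stat = stat,
             p = p, test = "glmm_score", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Wald test by refitting the logistic mixed model with the SNP
#'
#' The PQL fit is repeated with the dosage appended to the fixed effects;
#' the Wald p-value for its coefficient comes from the working-model
#' covariance at convergence. Intended for the top SNPs of a score-test
#' scan (the two-round protocol), not for genome-wide use.
#'
#' @param y_bin,X,K as in [fit_glmm_null()].
#' @param g dosage vector.
#' @return one-row data frame `maf, beta, se, stat, p, test, note`.
#' @export
glmm_wald_refit <- function(y_bin, X, K, g) {
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (sd(g) == 0)
    return(data.frame(maf = NA_real_, beta = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, test = "glmm_wald",
                      note = "monomorphic", stringsAsFactors = FALSE))
  af <- mean(g) / 2
  Xg <- cbind(X, snp = g)
  fit <- fit_glmm_null(y_bin, Xg, K)
  if (!fit$converged)
    return(data.frame(maf = min(af, 1 - af), beta = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, test = "glmm_wald",
                      note = "not converged", stringsAsFactors = FALSE))
  j <- ncol(Xg)
  se <- sqrt(solve(fit$XtViX)[j, j])
  zst <- fit$beta[j] / se
  data.frame(maf = min(af, 1 - af), beta = unname(fit$beta[j]), se = se,
             stat = zst, p = 2 * pnorm(-abs(zst)), test = "glmm_wald",
             note = "", stringsAsFactors = FALSE)
}
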