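#' Remove zero trait values
#'
#' Linear mixed-model association assumes continuous residuals, and a
#' point mass at zero violates that; zero-valued genotypes are therefore
#' excluded before transformation and kept track of by index.
#'
#' @param x numeric vector.
#' @param tol values below `tol` count as zero.
#' @return list with `values` (strictly positive subset) and `kept`
#'   (indices into `x`).
#' @export
drop_zeros <- function(x, tol = 1e-12) {
  kept <- which(!is.na(x) & x >= tol)
  if (length(kept) == 0L)
    warning("all values are zero or missing; nothing retained")
  list(values = x[kept], kept = kept)
}

#' Box-Cox transformation by profile maximum likelihood
#'
#' Profiles the Box-Cox log-likelihood
#' \deqn{\ell(\lambda) = -\tfrac{n}{2}\log\hat\sigma^2(\lambda) + (\lambda - 1)\sum \log x_i}
#' over a grid and polishes the maximum with `optimize()`. The transform is
#' \eqn{(x^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0} and \eqn{\log x}
#' at \eqn{\lambda = 0}.
#'
#' @param x strictly positive numeric vector, `n >= 10`.
#' @param lambda_range interval searched for the power parameter.
#' @param grid_n grid resolution for the returned profile curve.
#' @return list with `lambda`, `transformed`, and `profile` (data frame of
#'   `lambda`, `loglik`).
#' @export
boxcox_mle <- function(x, lambda_range = c(-2, 2), grid_n = 201L) {
  x <- x[!is.na(x)]
  if (length(x) < 10L) stop("need at least 10 observations", call. = FALSE)
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values", call. = FALSE)
  if (sd(x) == 0) stop("constant input: Box-Cox likelihood is degenerate",
                       call. = FALSE)
  n <- length(x); slx <- sum(log(x))
  ll <- function(l) {
    y <- boxcox_apply(x, l)
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
  }
  grid <- seq(lambda_range[1], lambda_range[2], length.out = grid_n)
  prof <- vapply(grid, ll, numeric(1))
  i <- which.max(prof)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE)
  lambda <- opt$maximum
  list(lambda = lambda, transformed = boxcox_apply(x, lambda),
       profile = data.frame(lambda = grid, loglik = prof))
}

#' @rdname boxcox_mle
#' @param lambda power parameter.
#' @export
boxcox_apply <- function(x, lambda) {
  if (abs(lambda) < 1e-10) log(x) else (x^lambda - 1) / lambda
}

#' Rank-based inverse-normal transformation
#'
#' Blom scores: \eqn{z_i = \Phi^{-1}((r_i - 3/8)/(n + 1/4))} with ties
#' sharing mid-ranks. Missing values stay missing and do not consume ranks.
#'
#' @param x numeric vector.
#' @param c_offset rank offset; 3/8 (Blom) by default.
#' @return numeric vector of normal scores.
#' @export
rank_inverse_normal <- function(x, c_offset = 3 / 8) {
  z <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  z[ok] <- qnorm((r - c_offset) / (n - 2 * c_offset + 1))
  z
}

#' Elbow cutoff from the second derivative of the density
#'
#' Estimates the trait's frequency distribution with a Gaussian kernel
#' density (Silverman bandwidth, 512-point grid spanning the data) and
#' looks for the "elbow" separating a spike of degenerate low values from
#' the main mass: the grid point with the largest finite-difference
#' second derivative, searched strictly between the leftmost and
#' rightmost local modes of the density. A unimodal density has no such
#' region, and a proposed cutoff below the 1st percentile of the data is
#' treated the same way: no elbow, no removal.
#'
#' @param x numeric vector, `n >= 50`.
#' @param grid_n density grid size.
#' @return list with `cutoff` (numeric or `NA`), `apply` (logical: remove
#'   values below the cutoff?), and `n_below`.
#' @export
elbow_threshold <- function(x, grid_n = 512L) {
  x <- x[!is.na(x)]
  if (length(x) < 50L) stop("need at least 50 observations", call. = FALSE)
  d <- density(x, bw = "nrd0", n = grid_n, from = min(x), to = max(x))
  y <- d$y
  is_mode <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_mode <- c(1L, is_mode)
  if (y[grid_n] > y[grid_n - 1L]) is_mode <- c(is_mode, grid_n)
  if (length(is_mode) < 2L || max(is_mode) - min(is_mode) < 4L) {
    warning("density is unimodal; no elbow, no removal")
    return(list(cutoff = NA_real_, apply = FALSE, n_below = 0L))
  }
  span <- seq(min(is_mode), max(is_mode))
  d2 <- diff(y[span], differences = 2L)
  cut_i <- span[which.max(d2) + 1L]
  cutoff <- d$x[cut_i]
  appl <- cutoff >= quantile(x, 0.01)
  if (!appl)
    warning("elbow below the 1st percentile; treating as no elbow, no removal")
  list(cutoff = cutoff, apply = appl, n_below = sum(x < cutoff))
}

#' Normality diagnostics for a trait
#'
#' Shapiro-Wilk test plus the Pearson correlation of the sorted sample
#' against theoretical quantiles of a normal with the sample's own mean
#' and standard deviation.
#'
#' @param x numeric vector, `n >= 3`.
#' @return list with `W`, `p_value`, `r_normal`, `n`.
#' @export
normality_report <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  sw <- shapiro.test(x)
  theo <- qnorm(ppoints(n), mean = mean(x), sd = sd(x))
  list(W = unname(sw$statistic), p_value = sw$p.value,
       r_normal = cor(sort(x), theo), n = n)
}

#' Dichotomize a zero-inflated trait
#'
#' @param x numeric vector.
#' @param tol values below `tol` count as zero.
#' @return integer vector (0 = zero trait, 1 = nonzero), `NA` preserved.
#' @export
dichotomize <- function(x, tol = 1e-12) {
  y <- ifelse(is.na(x), NA_integer_, as.integer(x >= tol))
  if (length(unique(y[!is.na(y)])) < 2L)
    warning("dichotomized trait has no variation")
  y
}

#' Derived traits by PCA over a batch of timepoint traits
#'
#' Centered, unscaled principal component analysis over a batch of traits
#' (callus timepoints, shoot timepoints, or both): the traits share the
#' proportion-of-plant-area scale, so rescaling is deliberately not
#' performed. Genotypes with any missing value in the batch are excluded,
#' as are genotypes that are zero across the whole batch (these form a
#' degenerate spike in PC space). PC1 and PC2 scores are returned as
#' derived traits; later components are not analyzed.
#'
#' @param trait_mat numeric matrix, genotypes x traits, with genotype IDs
#'   as row names.
#' @param n_pc number of leading components to return as traits.
#' @return list with `scores`, `loadings`, `variance_explained` (fractions),
#'   `included_genotypes`, `n_dropped_missing`, `n_dropped_allzero`.
#' @export
trait_pca <- function(trait_mat, n_pc = 2L) {
  trait_mat <- as.matrix(trait_mat)
  if (ncol(trait_mat) < 2L) stop("need at least 2 traits", call. = FALSE)
  complete <- rowSums(is.na(trait_mat)) == 0L
  allzero <- complete & rowSums(trait_mat != 0, na.rm = TRUE) == 0L
  keep <- complete & !allzero
  if (sum(keep) < 10L) stop("need at least 10 complete genotypes", call. = FALSE)
  pc <- prcomp(trait_mat[keep, , drop = FALSE], center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(n_pc, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_pc), drop = FALSE],
       loadings = pc$rotation,
       variance_explained = ve,
       included_genotypes = rownames(trait_mat)[keep],
       n_dropped_missing = sum(!complete),
       n_dropped_allzero = sum(allzero))
}

#' Apply a per-trait transformation recipe
#'
#' Chains the preparation steps the association methods expect: zero
#' removal, optional elbow thresholding, optional outlier removal on the
#' transformed scale (|z| > `outlier_z`), and a Box-Cox or rank
#' inverse-normal transform. Counts removed at each step are logged so an
#' audit of the pipeline adds up.
#'
#' @param x named numeric vector (names = genotype IDs).
#' @param method `"boxcox"`, `"rbinv"`, or `"none"` (zero removal only).
#' @param drop_zero remove zeros first (required for `"boxcox"`).
#' @param elbow apply [elbow_threshold()] removal before transforming.
#' @param outlier_z remove transformed values with |z| above this; `Inf`
#'   disables.
#' @return list with `values` (transformed, named), `kept` (indices into
#'   `x`), and `audit` (named counts removed per step plus parameters).
#' @export
transform_trait <- function(x, method = c("boxcox", "rbinv", "none"),
                            drop_zero = TRUE, elbow = FALSE, outlier_z = 4) {
  method <- match.arg(method)
  ids <- names(x); if (is.null(ids)) ids <- as.character(seq_along(x))
  kept <- which(!is.na(x))
  audit <- list(n_input = length(x), n_missing = sum(is.na(x)))
  v <- x[kept]
  if (drop_zero || method == "boxcox") {
    dz <- drop_zeros(v)
    audit$n_zero <- length(v) - length(dz$kept)
    kept <- kept[dz$kept]; v <- dz$values
  }
  if (elbow && length(v) >= 50L) {
    el <- elbow_threshold(v)
    if (el$apply) {
      keep_i <- which(v >= el$cutoff)
      audit$n_elbow <- length(v) - length(keep_i)
      audit$elbow_cutoff <- el$cutoff
      kept <- kept[keep_i]; v <- v[keep_i]
    } else audit$n_elbow <- 0L
  }
  lambda <- NULL
  tv <- switch(method,
    boxcox = { bc <- boxcox_mle(v); lambda <- bc$lambda; bc$transformed },
    rbinv = rank_inverse_normal(v),
    none = v)
  if (is.finite(outlier_z) && length(tv) > 2L) {
    z <- (tv - mean(tv)) / sd(tv)
    keep_i <- which(abs(z) <= outlier_z)
    audit$n_outlier <- length(tv) - length(keep_i)
    kept <- kept[keep_i]; tv <- tv[keep_i]
    if (method == "rbinv" && audit$n_outlier > 0) tv <- rank_inverse_normal(tv)
  }
  audit$method <- method
  if (!is.null(lambda)) audit$lambda <- lambda
  audit$n_final <- length(tv)
  names(tv) <- ids[kept]
  list(values = tv, kept = kept, audit = audit)
}
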