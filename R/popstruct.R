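#' Genomic relationship matrix
#'
#' Centered GRM: `K = Z Z' / m` over the `m` SNPs passing the MAF filter,
#' with `Z` the column-centered dosage matrix and missing dosages
#' mean-imputed per SNP. This matches the "centered relatedness" used by
#' standard mixed-model GWAS tools; a standardized variant (columns also
#' divided by their SD) is available by flag.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum MAF for a SNP to contribute.
#' @param standardize divide centered columns by their standard deviation.
#' @return an object of class `kinship`: list with `K` (n x n symmetric),
#'   `method`, `m` (SNPs used).
#' @export
compute_grm <- function(G, maf_min = 0.01, standardize = FALSE) {
  maf <- snp_maf(G)
  use <- which(!is.na(maf) & maf >= maf_min & !is_monomorphic(G))
  if (length(use) == 0L)
    stop("no SNPs pass the MAF filter; cannot form a GRM", call. = FALSE)
  Z <- G$dosages[, use, drop = FALSE]
  storage.mode(Z) <- "double"
  mu <- colMeans(Z, na.rm = TRUE)
  for (j in seq_along(use)) {
    z <- Z[, j]; z[is.na(z)] <- mu[j]
    Z[, j] <- z - mu[j]
  }
  if (standardize) Z <- sweep(Z, 2L, apply(Z, 2L, sd), "/")
  K <- tcrossprod(Z) / length(use)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  structure(list(K = K,
                 method = if (standardize) "standardized" else "centered",
                 m = length(use)),
            class = "kinship")
}

#' Sample principal components from SNP data
#'
#' Structure covariates for the "P model": eigenvectors of the GRM scaled
#' by the square root of their eigenvalues. Sign convention: within each
#' component the loading with the largest magnitude is positive, so the
#' output is deterministic.
#'
#' @param G a [genotype_matrix()].
#' @param k number of components.
#' @param maf_min MAF filter forwarded to [compute_grm()].
#' @return numeric matrix (samples x k) with eigenvalue fractions as
#'   attribute `"varprop"`.
#' @export
genotype_pca <- function(G, k = 5L, maf_min = 0.01) {
  kin <- compute_grm(G, maf_min = maf_min)
  ev <- eigen(kin$K, symmetric = TRUE)
  pos <- sum(ev$values > 1e-8 * max(ev$values))
  if (k > pos)
    stop("requested ", k, " PCs but the GRM has rank ", pos, call. = FALSE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(V, 2L, sqrt(ev$values[seq_len(k)]), "*")
  dimnames(scores) <- list(G$sample_ids, paste0("PC", seq_len(k)))
  attr(scores, "varprop") <- ev$values[seq_len(k)] / sum(pmax(ev$values, 0))
  scores
}

#' Linkage-disequilibrium decay curve
#'
#' Squared Pearson correlation of dosages for every intra-chromosomal SNP
#' pair closer than `max_dist`, averaged within distance bins, with a
#' cubic smoothing spline through the bin means. Empty bins are omitted
#' rather than reported as zero.
#'
#' @param G a [genotype_matrix()].
#' @param max_dist maximum pair distance in bp.
#' @param bin_width bin width in bp.
#' @return list with `bins` (data frame `dist_lo, dist_hi, mid, mean_r2,
#'   n_pairs`) and `spline` (a `smooth.spline` fit over the bin means, or
#'   `NULL` if fewer than 4 bins).
#' @export
ld_decay <- function(G, max_dist = 10000, bin_width = 500) {
  res <- list(); ri <- 1L
  for (ch in unique(G$chrom)) {
    idx <- which(G$chrom == ch)
    if (length(idx) < 2L) next
    pos <- G$pos[idx]
    X <- G$dosages[, idx, drop = FALSE]
    storage.mode(X) <- "double"
    for (a in seq_len(length(idx) - 1L)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist) {
        r <- suppressWarnings(cor(X[, a], X[, b], use = "complete.obs"))
        if (!is.na(r)) {
          res[[ri]] <- c(pos[b] - pos[a], r * r); ri <- ri + 1L
        }
        b <- b + 1L
      }
    }
  }
  if (length(res) == 0L)
    return(list(bins = data.frame(dist_lo = numeric(0), dist_hi = numeric(0),
                                  mid = numeric(0), mean_r2 = numeric(0),
                                  n_pairs = integer(0)),
                spline = NULL))
  pr <- do.call(rbind, res)
  bin <- floor((pr[, 1] - 1) / bin_width)
  agg <- tapply(pr[, 2], bin, mean)
  cnt <- tapply(pr[, 2], bin, length)
  b0 <- as.numeric(names(agg))
  bins <- data.frame(dist_lo = b0 * bin_width + 1,
                     dist_hi = (b0 + 1) * bin_width,
                     mid = b0 * bin_width + bin_width / 2,
                     mean_r2 = as.numeric(agg),
                     n_pairs = as.integer(cnt))
  bins <- bins[order(bins$mid), ]
  rownames(bins) <- NULL
  spl <- if (nrow(bins) >= 4L)
    smooth.spline(bins$mid, bins$mean_r2, w = bins$n_pairs) else NULL
  list(bins = bins, spline = spl)
}
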