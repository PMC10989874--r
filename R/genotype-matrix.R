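#' Genotype matrix container
#'
#' A light S3 container for biallelic SNP dosages (0/1/2, `NA` for missing)
#' with per-SNP chromosome/position metadata and optional per-sample
#' subpopulation labels. Positions are 1-based and strictly increasing
#' within each chromosome.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns.
#' @param chrom character vector of chromosome labels, one per SNP.
#' @param pos integer vector of 1-based positions, one per SNP.
#' @param sample_ids character vector of sample names.
#' @param snp_ids character vector of SNP names; generated if `NULL`.
#' @param subpop optional per-sample subpopulation labels.
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, sample_ids = rownames(dosages),
                            snp_ids = NULL, subpop = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  m <- ncol(dosages)
  if (length(chrom) != m || length(pos) != m)
    stop("`chrom` and `pos` must have one entry per SNP column", call. = FALSE)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- sprintf("%s_%d", chrom, pos)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, chrom = as.character(chrom),
                 pos = as.integer(pos), sample_ids = sample_ids,
                 snp_ids = snp_ids, subpop = subpop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%", 100 * miss))
  if (!is.null(x$subpop))
    cat(sprintf("; subpopulations: %d", length(unique(x$subpop))))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequency per SNP
#'
#' Computed over non-missing calls. SNPs with no non-missing call get `NA`.
#'
#' @param G a [genotype_matrix()].
#' @return numeric vector of MAFs in `[0, 0.5]`.
#' @export
snp_maf <- function(G) {
  af <- colMeans(G$dosages, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Flag monomorphic SNPs
#'
#' @param G a [genotype_matrix()].
#' @return logical vector, `TRUE` where the SNP carries no variation among
#'   non-missing calls.
#' @export
is_monomorphic <- function(G) {
  apply(G$dosages, 2L, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0L || all(g == g[1L])
  })
}

#' Subset a genotype matrix by SNPs and/or samples
#'
#' @param G a [genotype_matrix()].
#' @param snps SNP index (integer/logical) to keep; `NULL` keeps all.
#' @param samples sample index to keep; `NULL` keeps all.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(G, snps = NULL, samples = NULL) {
  if (is.null(snps)) snps <- seq_len(ncol(G$dosages))
  if (is.null(samples)) samples <- seq_len(nrow(G$dosages))
  genotype_matrix(G$dosages[samples, snps, drop = FALSE],
                  chrom = G$chrom[snps], pos = G$pos[snps],
                  sample_ids = G$sample_ids[samples],
                  snp_ids = G$snp_ids[snps],
                  subpop = if (is.null(G$subpop)) NULL else G$subpop[samples])
}
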