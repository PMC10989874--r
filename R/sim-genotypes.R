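#' Simulate genotypes for a structured population
#'
#' Draws SNP dosages under the Balding-Nichols model: each SNP has an
#' ancestral allele frequency `p ~ Uniform(maf_range)`, each subpopulation
#' draws its own frequency from `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`
#' (degenerating to `p` when `Fst = 0`), and each sample draws a
#' `Binomial(2, subpop frequency)` dosage. Positions are sampled uniformly
#' without replacement along each chromosome and sorted, giving a mean
#' inter-SNP spacing of `cfg$mean_spacing_bp`.
#'
#' When `cfg$ld_rho > 0`, an optional LD layer copies each sample's dosage
#' from the adjacent upstream SNP with probability
#' `ld_rho * exp(-distance / ld_scale_bp)`, producing correlation that
#' decays with distance; it is off by default because the target population
#' has near-zero LD beyond a couple of kilobases.
#'
#' The output is a deterministic function of `cfg` (including `cfg$seed`).
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with per-sample `subpop` labels.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_snps; K <- cfg$n_subpops

  # map SNPs onto chromosomes with strictly increasing positions
  per_chrom <- diff(round(seq(0, m, length.out = cfg$n_chrom + 1L)))
  chrom <- rep(sprintf("chr%02d", seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(mc) {
    L <- max(mc * cfg$mean_spacing_bp, mc + 1L)
    sort(sample.int(L, mc))
  }), use.names = FALSE)

  subpop <- sort(rep_len(seq_len(K), n))
  p_anc <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  if (cfg$fst > 0) {
    a <- p_anc * (1 - cfg$fst) / cfg$fst
    b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
    # K x m matrix of subpopulation frequencies
    p_sub <- matrix(rbeta(K * m, rep(a, each = K), rep(b, each = K)), nrow = K)
  } else {
    p_sub <- matrix(rep(p_anc, each = K), nrow = K)
  }

  dos <- matrix(rbinom(n * m, 2L, p_sub[subpop, ]), nrow = n)

  if (cfg$ld_rho > 0) {
    same <- c(FALSE, chrom[-1L] == chrom[-m])
    dist <- c(NA_integer_, diff(pos))
    for (j in which(same)) {
      r <- cfg$ld_rho * exp(-dist[j] / cfg$ld_scale_bp)
      copy <- runif(n) < r
      dos[copy, j] <- dos[copy, j - 1L]
    }
  }

  if (cfg$missing_rate > 0) {
    drop <- runif(n * m) < cfg$missing_rate
    dos[drop] <- NA_integer_
  }

  G <- genotype_matrix(dos, chrom = chrom, pos = pos,
                       sample_ids = sprintf("S%04d", seq_len(n)),
                       subpop = sprintf("pop%d", subpop))
  attr(G, "p_ancestral") <- p_anc
  attr(G, "p_subpop") <- p_sub
  G
}
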