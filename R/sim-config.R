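#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. The defaults describe the kind of population the pipeline is
#' aimed at: a structured wild tree population (several ancestral
#' subpopulations, moderate divergence, rapid LD decay) phenotyped for
#' zero-inflated regeneration proportions with stem-diameter and
#' phenotyping-phase covariates and two replicates per genotype.
#'
#' @param n_samples number of genotypes.
#' @param n_snps number of biallelic SNPs.
#' @param n_subpops number of ancestral subpopulations (the field data this
#'   emulates supports six or seven).
#' @param fst divergence of subpopulation allele frequencies from the
#'   ancestral frequency, in `[0, 1)`. `0` gives an unstructured population.
#' @param maf_range range from which ancestral allele frequencies are drawn
#'   uniformly.
#' @param n_chrom number of chromosomes; SNPs are split evenly.
#' @param mean_spacing_bp mean distance between adjacent SNPs, used to set
#'   chromosome lengths.
#' @param causal_loci data frame with columns `snp` (index) and `beta`
#'   (effect per standardized dosage), or `NULL` for no planted signal.
#' @param h2_poly polygenic fraction of liability variance, via a random
#'   effect with covariance proportional to the realized GRM.
#' @param zero_threshold liability cut below which the observed trait is
#'   exactly zero. On the standardized liability scale, so the expected
#'   zero fraction is `pnorm(zero_threshold)` when covariate effects and
#'   timepoint offsets are zero.
#' @param covariate_effects list with elements `diameter` (slope per SD of
#'   log stem diameter) and `phase` (numeric offsets, one per phase).
#' @param n_phases number of phenotyping phases.
#' @param phase_subpop_mixing probability that a genotype's phase is tied to
#'   its subpopulation rather than drawn at random; nonzero values confound
#'   phase with ancestry, which is what makes structure correction testable.
#' @param timepoint_offsets additions to `zero_threshold` per week (weeks
#'   2-5); positive early offsets emulate sparser regeneration at early
#'   timepoints.
#' @param n_replicates replicate plants per genotype. Replicates share the
#'   genetic and covariate parts of the liability and differ by independent
#'   residual noise.
#' @param ld_rho adjacent-SNP copying probability at zero distance for the
#'   optional LD simulator; `0` (default) gives independent SNPs.
#' @param ld_scale_bp distance scale of LD decay for the copier.
#' @param missing_rate fraction of dosage calls set missing at random.
#' @param seed integer seed; every generator output is a deterministic
#'   function of the configuration including this seed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 300L,
                       n_snps = 2000L,
                       n_subpops = 6L,
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       n_chrom = 2L,
                       mean_spacing_bp = 200,
                       causal_loci = NULL,
                       h2_poly = 0.3,
                       zero_threshold = 0,
                       covariate_effects = list(diameter = 0.2,
                                                phase = c(0, 0.15, -0.15, 0.1)),
                       n_phases = 4L,
                       phase_subpop_mixing = 0.5,
                       timepoint_offsets = c(0.6, 0.25, 0, -0.15),
                       n_replicates = 2L,
                       ld_rho = 0,
                       ld_scale_bp = 1000,
                       missing_rate = 0,
                       seed = 1L) {
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0 || fst >= 1)
    stop("`fst` must be a single value in [0, 1)", call. = FALSE)
  if (n_subpops < 1L)
    stop("`n_subpops` must be >= 1", call. = FALSE)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("`maf_range` must be an increasing pair within (0, 0.5]", call. = FALSE)
  if (h2_poly < 0 || h2_poly >= 1)
    stop("`h2_poly` must be in [0, 1)", call. = FALSE)
  if (!is.null(causal_loci)) {
    causal_loci <- as.data.frame(causal_loci)
    stopifnot(all(c("snp", "beta") %in% names(causal_loci)))
    if (any(causal_loci$snp < 1L | causal_loci$snp > n_snps))
      stop("causal SNP index out of range", call. = FALSE)
  }
  explained <- if (is.null(causal_loci)) 0 else sum(causal_loci$beta^2)
  if (h2_poly + explained > 1)
    stop("h2_poly plus variance explained by causal loci exceeds 1", call. = FALSE)
  if (length(covariate_effects$phase) != n_phases)
    stop("`covariate_effects$phase` must have one offset per phase", call. = FALSE)

  structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    n_subpops = as.integer(n_subpops), fst = fst, maf_range = maf_range,
    n_chrom = as.integer(n_chrom), mean_spacing_bp = mean_spacing_bp,
    causal_loci = causal_loci, h2_poly = h2_poly,
    zero_threshold = zero_threshold, covariate_effects = covariate_effects,
    n_phases = as.integer(n_phases), phase_subpop_mixing = phase_subpop_mixing,
    timepoint_offsets = timepoint_offsets,
    n_replicates = as.integer(n_replicates),
    ld_rho = ld_rho, ld_scale_bp = ld_scale_bp,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}
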