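#' Simulate zero-inflated regeneration traits on a liability scale
#'
#' Builds a standardized liability
#' \deqn{L = \sum_j b_j \tilde g_j + u + X\beta_{cov} + \varepsilon}
#' where \eqn{\tilde g_j} are standardized dosages of the planted causal
#' SNPs, \eqn{u} is a polygenic effect with covariance proportional to the
#' realized GRM of `G` and variance `cfg$h2_poly`, \eqn{X\beta_{cov}}
#' carries the stem-diameter slope and phenotyping-phase offsets, and
#' \eqn{\varepsilon} is drawn independently per replicate with the variance
#' that brings the genetic-plus-residual total to one. The observed trait
#' at a timepoint is zero when the liability falls below the (timepoint
#' shifted) threshold `cfg$zero_threshold`, otherwise the positive
#' liabilities are affinely rescaled into a proportion-of-plant-area range
#' (callus up to 0.7, shoot up to 0.3, so the two can never exceed the
#' whole plant). With covariate effects and timepoint offsets at zero,
#' the expected zero fraction is `pnorm(cfg$zero_threshold)`.
#'
#' Callus area carries the planted causal signal; shoot area shares half
#' the polygenic effect, carries no causal SNPs, and uses a higher
#' threshold, mimicking the sparser shoot regeneration seen in real
#' screens.
#'
#' @param G a [genotype_matrix()], normally from [simulate_genotypes()].
#' @param cfg the [sim_config()] used to generate `G`.
#' @return a trait table: one row per genotype x replicate x timepoint with
#'   columns `genotype_id, replicate, timepoint, callus_area, shoot_area,
#'   diameter, phase`. Timepoints are weeks 2-5. The per-genotype liability
#'   components are attached as attribute `"liability"` for downstream
#'   verification.
#' @export
simulate_traits <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  n <- nrow(G$dosages)
  set.seed(cfg$seed + 1L)

  # fixed genetic part from planted causal SNPs (standardized dosages)
  gf <- numeric(n)
  if (!is.null(cfg$causal_loci)) {
    if (any(cfg$causal_loci$snp > ncol(G$dosages)))
      stop("causal SNP index out of range for this genotype matrix", call. = FALSE)
    for (i in seq_len(nrow(cfg$causal_loci))) {
      g <- G$dosages[, cfg$causal_loci$snp[i]]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      s <- sd(g)
      if (s == 0) stop("causal SNP is monomorphic", call. = FALSE)
      gf <- gf + cfg$causal_loci$beta[i] * (g - mean(g)) / s
    }
  }

  # polygenic effect with GRM covariance, scaled to variance h2_poly
  u <- numeric(n)
  if (cfg$h2_poly > 0) {
    A <- compute_grm(G, maf_min = 0.01)$K
    A <- A / mean(diag(A))
    R <- chol(A + diag(1e-6, n))
    u <- sqrt(cfg$h2_poly) * drop(crossprod(R, rnorm(n)))
  }

  diameter <- rlnorm(n, meanlog = log(8), sdlog = 0.25)
  subpop_idx <- if (is.null(G$subpop)) rep(1L, n) else as.integer(factor(G$subpop))
  tied <- runif(n) < cfg$phase_subpop_mixing
  phase <- ifelse(tied, (subpop_idx - 1L) %% cfg$n_phases + 1L,
                  sample.int(cfg$n_phases, n, replace = TRUE))
  covpart <- cfg$covariate_effects$diameter *
    as.numeric(scale(log(diameter))) +
    cfg$covariate_effects$phase[phase]

  s2e <- 1 - cfg$h2_poly -
    (if (is.null(cfg$causal_loci)) 0 else sum(cfg$causal_loci$beta^2))

  weeks <- 2:5
  rows <- vector("list", cfg$n_replicates)
  for (rep_i in seq_len(cfg$n_replicates)) {
    eps <- rnorm(n, sd = sqrt(max(s2e, 0)))
    L_cal <- gf + u + covpart + eps
    eps2 <- rnorm(n, sd = sqrt(max(1 - cfg$h2_poly / 4, 0)))
    L_sho <- u / 2 + covpart + eps2
    per_week <- lapply(seq_along(weeks), function(t) {
      tau_c <- cfg$zero_threshold + cfg$timepoint_offsets[t]
      tau_s <- tau_c + 0.8
      data.frame(genotype_id = G$sample_ids, replicate = rep_i,
                 timepoint = weeks[t],
                 callus_area = squash_liability(L_cal, tau_c, upper = 0.7),
                 shoot_area = squash_liability(L_sho, tau_s, upper = 0.3),
                 diameter = diameter, phase = factor(phase),
                 stringsAsFactors = FALSE)
    })
    rows[[rep_i]] <- do.call(rbind, per_week)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "liability") <- data.frame(genotype_id = G$sample_ids,
                                       genetic = gf, polygenic = u,
                                       covariate = covpart)
  out
}

# Map liabilities to a zero-inflated proportion: exact zero below the
# threshold, else an affine rescale of (L - tau) into (0, upper]. A
# non-finite tau (no zero inflation) anchors the rescale just below the
# minimum. Callus uses upper = 0.7 and shoot upper = 0.3 so the two
# proportions can never sum past the whole plant area.
squash_liability <- function(L, tau, upper = 1) {
  ref <- if (is.finite(tau)) tau else min(L) - 1e-8
  pos <- L >= ref
  out <- numeric(length(L))
  if (any(pos)) {
    span <- max(L[pos] - ref)
    if (span <= 0) span <- 1
    out[pos] <- upper * (L[pos] - ref) / span
    out[pos][out[pos] == 0] <- .Machine$double.eps
  }
  out
}
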