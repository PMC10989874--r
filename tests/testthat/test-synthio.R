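test_that("genotype simulation is deterministic and respects fst = 0", {
  cfg <- sim_config(n_samples = 4L, n_snps = 3L, n_subpops = 2L,
                    fst = 0.2, seed = 11L)
  G1 <- simulate_genotypes(cfg)
  G2 <- simulate_genotypes(cfg)
  expect_identical(G1$dosages, G2$dosages)
  expect_identical(G1$pos, G2$pos)

  cfg0 <- sim_config(n_samples = 10L, n_snps = 50L, n_subpops = 3L,
                     fst = 0, seed = 5L)
  G0 <- simulate_genotypes(cfg0)
  ps <- attr(G0, "p_subpop")
  expect_true(all(ps == rep(attr(G0, "p_ancestral"), each = 3L)))
})

test_that("config validation rejects bad divergence and causal settings", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_config(causal_loci = data.frame(snp = 5000, beta = 1),
                          n_snps = 100), "out of range")
  expect_error(sim_config(h2_poly = 0.8,
                          causal_loci = data.frame(snp = 1, beta = 0.6)),
               "exceeds 1")
})

test_that("realized divergence matches the Hudson Fst oracle", {
  cfg <- sim_config(n_samples = 400L, n_snps = 5000L, n_subpops = 2L,
                    fst = 0.1, n_chrom = 2L, seed = 9L)
  G <- simulate_genotypes(cfg)
  expect_lt(abs(hudson_fst(G) - 0.1), 0.03)
})

test_that("realized MAFs respect the configured range and monomorphic flagging", {
  cfg <- sim_config(n_samples = 250L, n_snps = 800L, fst = 0.05,
                    maf_range = c(0.2, 0.5), seed = 3L)
  G <- simulate_genotypes(cfg)
  maf <- snp_maf(G)
  # sampling noise around a Uniform(0.2, 0.5) ancestral draw
  expect_gt(mean(maf >= 0.15), 0.97)
  expect_false(any(is_monomorphic(G)[maf > 0.05]))
})

test_that("positions are strictly increasing within chromosomes", {
  G <- small_pop()$G
  for (ch in unique(G$chrom))
    expect_true(all(diff(G$pos[G$chrom == ch]) > 0))
})

test_that("simulated proportions respect the plant-area budget", {
  fx <- small_pop()
  with(fx$traits, {
    expect_true(all(callus_area >= 0 & callus_area <= 1))
    expect_true(all(shoot_area >= 0 & shoot_area <= 1))
    expect_true(all(callus_area + shoot_area <= 1))
  })
})

test_that("trait zero fraction tracks the liability threshold", {
  base <- list(n_samples = 800L, n_snps = 200L, fst = 0.05, h2_poly = 0.2,
               covariate_effects = list(diameter = 0, phase = rep(0, 4)),
               timepoint_offsets = rep(0, 4), n_replicates = 1L)
  cfg_inf <- do.call(sim_config, c(base, list(zero_threshold = -Inf, seed = 2L)))
  G <- simulate_genotypes(cfg_inf)
  tr <- simulate_traits(G, cfg_inf)
  expect_identical(sum(tr$callus_area == 0), 0L)

  cfg0 <- do.call(sim_config, c(base, list(zero_threshold = 0, seed = 2L)))
  tr0 <- simulate_traits(G, cfg0)
  z <- mean(tr0$callus_area[tr0$timepoint == 4] == 0)
  ci <- qbinom(c(0.0005, 0.9995), 800, 0.5) / 800
  expect_gt(z, ci[1]); expect_lt(z, ci[2])
})

test_that("traits are uncorrelated with SNPs under a pure-noise model", {
  cfg <- sim_config(n_samples = 400L, n_snps = 300L, fst = 0.02,
                    h2_poly = 0, zero_threshold = -Inf,
                    covariate_effects = list(diameter = 0, phase = rep(0, 4)),
                    phase_subpop_mixing = 0, timepoint_offsets = rep(0, 4),
                    n_replicates = 1L, seed = 21L)
  G <- simulate_genotypes(cfg)
  tr <- simulate_traits(G, cfg)
  y <- tr$callus_area[tr$timepoint == 4]
  cors <- abs(cor(y, G$dosages))
  expect_lt(mean(cors > 3 / sqrt(400)), 0.02)
})

test_that("causal index validation happens against the genotype matrix", {
  fx <- small_pop()
  cfg_bad <- fx$cfg
  cfg_bad$causal_loci <- data.frame(snp = 10000L, beta = 0.1)
  expect_error(simulate_traits(fx$G, cfg_bad), "out of range")
})

test_that("masks hit requested class proportions to within one pixel", {
  req <- data.frame(callus_area = c(0.1, 0), shoot_area = c(0.3, 0))
  masks <- simulate_masks(req, image_size = 64L, seed = 7L)
  n_plant <- sum(masks[[1]] != 0L)
  expect_identical(sum(masks[[1]] == 2L), as.integer(round(0.1 * n_plant)))
  expect_identical(sum(masks[[1]] == 3L), as.integer(round(0.3 * n_plant)))
  expect_setequal(unique(as.integer(masks[[2]])), c(0L, 1L))
  # round trip through the trait extractor
  pr <- mask_class_proportions(masks[[1]])
  expect_lt(abs(pr[["callus_area"]] - 0.1), 1 / n_plant + 1e-12)
  expect_lt(abs(pr[["shoot_area"]] - 0.3), 1 / n_plant + 1e-12)
  expect_error(simulate_masks(data.frame(callus_area = 0.8, shoot_area = 0.4)),
               "sum to at most 1")
})

test_that("VCF, GFF3 and CSV round trips are lossless", {
  fx <- small_pop()
  G <- fx$G
  G$dosages[1L, 3L] <- NA_integer_  # exercise the missing path
  tv <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, tv)
  G2 <- read_vcf(tv)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_identical(G2$pos, G$pos)
  expect_identical(G2$chrom, G$chrom)

  ann <- simulate_annotation(G, n_genes = 8L, seed = 2L)
  tg <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, tg)
  ann2 <- read_gff3(tg)
  expect_equal(ann2$genes[c("gene_id", "chrom", "start", "end", "strand")],
               ann$genes[c("gene_id", "chrom", "start", "end", "strand")],
               ignore_attr = TRUE)
  expect_equal(nrow(ann2$exons), nrow(ann$exons))

  tc <- withr::local_tempfile(fileext = ".csv")
  write_traits_csv(fx$traits, tc)
  tr2 <- read_traits_csv(tc)
  expect_equal(tr2$callus_area, fx$traits$callus_area, tolerance = 1e-12)
  expect_identical(as.character(tr2$phase), as.character(fx$traits$phase))
})

test_that("optional LD layer produces distance-decaying correlation", {
  cfg <- sim_config(n_samples = 300L, n_snps = 400L, n_chrom = 1L, fst = 0,
                    mean_spacing_bp = 100, ld_rho = 0.9, ld_scale_bp = 2000,
                    seed = 13L)
  G <- simulate_genotypes(cfg)
  ld <- ld_decay(G, max_dist = 5000, bin_width = 1000)
  expect_gt(nrow(ld$bins), 3L)
  expect_gt(ld$bins$mean_r2[1], ld$bins$mean_r2[nrow(ld$bins)])
})
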