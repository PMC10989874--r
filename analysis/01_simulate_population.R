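#!/usr/bin/env Rscript
# Stage 1: build the synthetic study population.
#
# A structured wild population (six subpopulations, Balding-Nichols
# divergence Fst = 0.1) is genotyped at 2,000 SNPs over two chromosomes;
# zero-inflated callus- and shoot-area traits are generated on a liability
# scale with a planted causal SNP, stem-diameter and phase covariates, and
# two replicates; a toy gene annotation provides targets for peak-to-gene
# assignment. Everything downstream reads the files written here.

suppressMessages(library(regenmap))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

# ld_rho/ld_scale give r^2 that decays to background within ~2 kb,
# mimicking the very rapid decay of an outcrossing tree population; the
# planted signal is a short causal block (a regulatory-region haplotype)
# rather than a lone SNP, the situation the window-combination stages
# are designed to exploit
cfg <- sim_config(n_samples = 300L, n_snps = 2000L, n_subpops = 6L,
                  fst = 0.1, h2_poly = 0.3, mean_spacing_bp = 30,
                  ld_rho = 0.9, ld_scale_bp = 800,
                  causal_loci = data.frame(snp = c(997L, 1000L, 1003L),
                                           beta = c(0.3, 0.35, 0.3)),
                  zero_threshold = 0, seed = 20240301L)

G <- simulate_genotypes(cfg)
message(sprintf("simulated %d samples x %d SNPs; causal block %s-%s",
                nrow(G$dosages), ncol(G$dosages), G$snp_ids[997],
                G$snp_ids[1003]))
write_vcf(G, "results/data/population.vcf")

traits <- simulate_traits(G, cfg)
zero_frac <- with(traits, tapply(callus_area == 0, timepoint, mean))
message("callus zero fraction by week: ",
        paste(sprintf("wk%d %.2f", as.integer(names(zero_frac)), zero_frac),
              collapse = ", "))
write_traits_csv(traits, "results/data/traits_replicates.csv")

ann <- simulate_annotation(G, n_genes = 20L, seed = cfg$seed)
write_gff3(ann, "results/data/genes.gff3")
message(sprintf("wrote %d toy genes", nrow(ann$genes)))

# a handful of masks matching week-4 trait rows, to exercise the imaging
# front end of the pipeline
wk4 <- traits[traits$timepoint == 4 & traits$replicate == 1, ][1:6, ]
masks <- simulate_masks(wk4, image_size = 64L, seed = cfg$seed)
for (i in seq_along(masks))
  write_mask_png(masks[[i]],
                 sprintf("results/data/mask_%s_wk4.png", wk4$genotype_id[i]))
message("wrote ", length(masks), " example segmentation masks")
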