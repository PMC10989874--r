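#!/usr/bin/env Rscript
# Stage 6: combination, thresholds, peaks, genes.
#
# ART combination of single-SNP p-values over 1 kb windows (two rounds for
# the logistic model: score p-values first, Wald refits for surviving
# windows), the three multiple-testing tiers, 30 kb peak deduplication and
# nearest-gene assignment with the 5 kb proximity flag.

suppressMessages(library(regenmap))

assoc_lmm <- read.table("results/assoc_lmm.tsv", header = TRUE, sep = "\t")
assoc_glmm <- read.table("results/assoc_glmm.tsv", header = TRUE, sep = "\t")
ann <- read_gff3("results/data/genes.gff3")
G <- read_vcf("results/data/population.vcf")

genome_bp <- sum(vapply(unique(G$chrom),
                        function(ch) max(G$pos[G$chrom == ch]), integer(1)))
art_thr <- art_bonferroni_threshold(genome_bp)
cons_thr <- conservative_bonferroni(nrow(assoc_lmm))
message(sprintf(
  "thresholds: conservative Bonferroni %.2e (%d tests), ART-Bonferroni %.2e (%d windows)",
  cons_thr, nrow(assoc_lmm), art_thr, genome_bp %/% 1000))

art_lmm <- art_apply(art_anchor_scan(assoc_lmm), art_thr)
message(sprintf("ART over LMM results: %d anchor windows, %d passing %.2e",
                nrow(art_lmm), sum(art_lmm$pass_threshold %in% TRUE), art_thr))
write.table(art_lmm[, setdiff(names(art_lmm), c("member_p", "member_pos"))],
            "results/art_lmm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# two-round ART over the logistic model: score p-values select windows,
# Wald refits price their members accurately, ART is recomputed
merged <- read_traits_csv("results/data/traits_merged.csv")
wk4 <- merged[merged$timepoint == 4, ]
wk4 <- wk4[match(G$sample_ids, wk4$genotype_id), ]
y_bin <- dichotomize(wk4$callus_area)
K <- read_kinship_tsv("results/data/kinship.tsv")
phase <- droplevels(factor(wk4$phase))
X <- model.matrix(~ scale(log(wk4$diameter)) + phase)
keep <- which(!is.na(y_bin))
wald_fun <- function(snp_id) {
  j <- match(snp_id, G$snp_ids)
  if (is.na(j)) return(NA_real_)
  glmm_wald_refit(y_bin[keep], X[keep, , drop = FALSE], K[keep, keep],
                  G$dosages[keep, j])$p
}
art_glmm <- art_two_round_gmmat(assoc_glmm, wald_fun, art_thr)
message(sprintf(
  "two-round ART over GLMM: %d score-based windows, %d confirmed by Wald refits",
  nrow(art_glmm$round1), sum(art_glmm$round2$pass_threshold %in% TRUE)))
drop_cols <- c("member_p", "member_pos")
write.table(art_glmm$round2[, setdiff(names(art_glmm$round2), drop_cols)],
            "results/art_glmm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# peaks and genes per method
peak_rows <- list()
for (m in c("lmm", "glmm")) {
  a <- if (m == "lmm") assoc_lmm else assoc_glmm
  a$tier <- threshold_tiers(a$p)
  pk <- find_peaks(a)
  gene <- do.call(rbind, lapply(seq_len(nrow(pk)), function(i)
    assign_gene(pk$chrom[i], pk$pos[i], ann)))
  peak_rows[[m]] <- cbind(method = m,
                          pk[, c("chrom", "pos", "p", "tier")], gene)
}
peaks <- do.call(rbind, peak_rows)
rownames(peaks) <- NULL
write.table(peaks, "results/peaks_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- peaks[peaks$tier != "none", , drop = FALSE]
message(sprintf("peaks: %d total, %d passing a threshold tier", nrow(peaks),
                nrow(sig)))
if (nrow(sig)) {
  tab <- summarize_tiers(sig)
  write.table(tab, "results/tier_summary.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  top <- sig[which.min(sig$p), ]
  message(sprintf(
    "top peak: %s:%d (p = %.2e, %s) -> %s, %s, %d bp from the TSS",
    top$chrom, top$pos, top$p, top$method, top$gene_id, top$relation,
    top$tss_distance))
}
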