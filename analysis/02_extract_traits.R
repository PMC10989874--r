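#!/usr/bin/env Rscript
# Stage 2: image-derived traits.
#
# Reads the example segmentation masks back from PNG, recovers callus- and
# shoot-area proportions, checks them against the trait table, then merges
# replicates for the full table and reports normality diagnostics that
# motivate the transformations of stage 3.

suppressMessages(library(regenmap))

traits <- read_traits_csv("results/data/traits_replicates.csv")

mask_files <- list.files("results/data", pattern = "^mask_.*\\.png$",
                         full.names = TRUE)
masks <- lapply(mask_files, read_mask_png)
ids <- sub("^mask_(.*)_wk4\\.png$", "\\1", basename(mask_files))
meta <- data.frame(genotype_id = ids, replicate = 1L, timepoint = 4L)
from_masks <- masks_to_traits(masks, meta)
ref <- traits[traits$timepoint == 4 & traits$replicate == 1, ]
cmp <- merge(from_masks, ref, by = "genotype_id",
             suffixes = c("_mask", "_table"))
message(sprintf("mask-recovered callus area matches the table within %.4f",
                max(abs(cmp$callus_area_mask - cmp$callus_area_table))))

merged <- merge_replicates(traits)
write_traits_csv(merged, "results/data/traits_merged.csv")
message(sprintf("merged %d replicate rows into %d genotype x week rows",
                nrow(traits), nrow(merged)))

# normality of the raw week-4 callus trait, zeros excluded
wk4 <- merged[merged$timepoint == 4, ]
pos <- drop_zeros(wk4$callus_area)$values
rep_raw <- normality_report(pos)
rep_inv <- normality_report(rank_inverse_normal(pos))
message(sprintf(
  "week-4 callus (nonzero n = %d): Shapiro W = %.3f (p = %.2g), r_normal = %.3f",
  rep_raw$n, rep_raw$W, rep_raw$p_value, rep_raw$r_normal))
message(sprintf("after rank inverse-normal: r_normal = %.3f", rep_inv$r_normal))
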