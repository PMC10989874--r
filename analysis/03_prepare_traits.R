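#!/usr/bin/env Rscript
# Stage 3: trait preparation.
#
# Applies the per-trait transformation recipes used before association:
# zero removal + Box-Cox and the rank inverse-normal alternative for the
# week-4 callus trait, dichotomization for the logistic model, and PCA
# over the callus/shoot timepoint batches to derive PC1/PC2 traits. A JSON
# audit records what each step removed.

suppressMessages(library(regenmap))
`%||%` <- function(a, b) if (is.null(a)) b else a

merged <- read_traits_csv("results/data/traits_merged.csv")
wk4 <- merged[merged$timepoint == 4, ]
y <- wk4$callus_area
names(y) <- wk4$genotype_id

audits <- list()
for (method in c("boxcox", "rbinv")) {
  tr <- transform_trait(y, method = method)
  audits[[method]] <- tr$audit
  out <- data.frame(genotype_id = names(tr$values), value = unname(tr$values))
  write.csv(out, sprintf("results/data/trait_callus_wk4_%s.csv", method),
            row.names = FALSE)
  message(sprintf(
    "callus wk4 %-6s: kept %d of %d (zeros removed %d, outliers %d)%s",
    method, tr$audit$n_final, tr$audit$n_input, tr$audit$n_zero,
    tr$audit$n_outlier %||% 0,
    if (method == "boxcox") sprintf(", lambda = %.2f", tr$audit$lambda) else ""))
}

y_bin <- dichotomize(y)
message(sprintf("dichotomized: %d regenerating / %d recalcitrant",
                sum(y_bin == 1, na.rm = TRUE), sum(y_bin == 0, na.rm = TRUE)))

# PC traits over the callus timepoint batch
wide <- reshape(merged[, c("genotype_id", "timepoint", "callus_area")],
                idvar = "genotype_id", timevar = "timepoint",
                direction = "wide")
mat <- as.matrix(wide[, -1])
rownames(mat) <- wide$genotype_id
pca <- trait_pca(mat)
audits$pca_callus <- list(n_dropped_missing = pca$n_dropped_missing,
                          n_dropped_allzero = pca$n_dropped_allzero,
                          variance_explained = pca$variance_explained)
message(sprintf(
  "callus PCA: PC1 %.0f%%, PC2 %.0f%% of variance; dropped %d all-zero genotypes",
  100 * pca$variance_explained[1], 100 * pca$variance_explained[2],
  pca$n_dropped_allzero))
write.csv(data.frame(genotype_id = pca$included_genotypes, pca$scores),
          "results/data/trait_callus_pcs.csv", row.names = FALSE)

jsonlite::write_json(audits, "results/data/transform_audit.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
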