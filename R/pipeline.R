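#' Default pipeline configuration
#'
#' All thresholds of the association pipeline in one place: anchor-scan
#' criteria (1e-5 anchor, 1e-4 neighbors, 500 bp, 5 neighbors), the 30 kb
#' peak rule and the 5 kb gene-proximity flag, FDR level 0.10, alpha 0.05,
#' 3 kb / 1 kb SKAT window geometry and the 1 kb ART window.
#'
#' @param ... overrides of the defaults.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    trait = "callus_area", timepoint = 4L, transform = "boxcox",
    elbow = FALSE, outlier_z = 4,
    maf_min = 0.05, miss_max = 0.10,
    n_pcs = 5L, structure_model = "P",
    h2_gate = 0.10, h2_override = TRUE,
    anchor_p = 1e-5, neighbor_p = 1e-4, neighbor_bp = 500L,
    min_neighbors = 5L, art_window_bp = 1000L,
    skat_width = 3000L, skat_step = 1000L, skat_beta = c(1, 25),
    skat_gate = 1e-3, skat_B_max = 1e4, skat_maf_min = 0.01,
    peak_radius = 30000L, proximal_bp = 5000L,
    fdr_q = 0.10, alpha = 0.05, genome_bp = NULL,
    seed = 1L, workers = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full association pipeline
#'
#' Orchestrates every stage: replicate merging, the per-trait
#' transformation recipe, kinship and genotype PCs, the three association
#' methods (mixed-model Wald on the transformed trait, logistic
#' mixed-model score on the dichotomized trait, windowed SKAT with
#' empirical p-values on the untransformed trait), ART combination of the
#' single-SNP results (two rounds for the logistic model), threshold
#' tiers, 30 kb peak deduplication, and nearest-gene assignment. Writes
#' deterministic TSVs plus a JSON audit log; with the same inputs, seed
#' and configuration the outputs are byte-identical regardless of the
#' worker count.
#'
#' @param G a [genotype_matrix()] or VCF path.
#' @param traits trait table (per-replicate) or CSV path.
#' @param annotation a `gene_annotation`, GFF3 path, or `NULL`.
#' @param outdir results directory (created if needed).
#' @param config list from [pipeline_config()].
#' @param qmatrix optional ancestry-fraction matrix (or TSV path) used as
#'   structure covariates when `config$structure_model == "Q"`.
#' @return invisibly, a list with the main result tables and file paths.
#' @export
run_pipeline <- function(G, traits, annotation = NULL, outdir,
                         config = pipeline_config(), qmatrix = NULL) {
  if (is.character(G)) G <- read_vcf(G)
  if (is.character(traits)) traits <- read_traits_csv(traits)
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  if (is.character(qmatrix)) qmatrix <- read_qmatrix(qmatrix)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  audit <- list(config = config[setdiff(names(config), "skat_beta")])

  ## trait preparation -------------------------------------------------
  merged <- merge_replicates(traits)
  sel <- merged[merged$timepoint == config$timepoint, , drop = FALSE]
  sel <- sel[match(G$sample_ids, sel$genotype_id), , drop = FALSE]
  y_raw <- sel[[config$trait]]
  names(y_raw) <- G$sample_ids
  audit$n_genotypes <- length(y_raw)
  audit$n_trait_missing <- sum(is.na(y_raw))
  audit$n_trait_zero <- sum(y_raw == 0, na.rm = TRUE)

  tr <- transform_trait(y_raw, method = config$transform,
                        elbow = config$elbow, outlier_z = config$outlier_z)
  audit$transform <- tr$audit

  ## covariates and structure ------------------------------------------
  phase <- droplevels(factor(sel$phase))
  X_all <- model.matrix(~ scale(log(diameter)) + phase,
                        data = data.frame(diameter = sel$diameter,
                                          phase = phase))
  colnames(X_all) <- c("intercept", "log_diameter",
                       paste0("phase", levels(phase)[-1]))
  kin <- compute_grm(G, maf_min = config$skat_maf_min)
  pcs <- genotype_pca(G, k = config$n_pcs, maf_min = config$skat_maf_min)
  struct_cov <- if (identical(config$structure_model, "Q") && !is.null(qmatrix))
    qmatrix[, -1, drop = FALSE]  # drop one column: fractions sum to 1
  else pcs

  ## mixed-model scan on the transformed trait -------------------------
  idx_lmm <- tr$kept
  null_lmm <- fit_lmm_null(unname(tr$values), X_all[idx_lmm, , drop = FALSE],
                           kin$K[idx_lmm, idx_lmm])
  audit$h2_snp <- null_lmm$h2
  run_lmm <- null_lmm$h2 > config$h2_gate || isTRUE(config$h2_override)
  audit$h2_gate_passed <- null_lmm$h2 > config$h2_gate
  assoc_lmm <- if (run_lmm)
    lmm_gwas(null_lmm, subset_genotypes(G, samples = idx_lmm),
             maf_min = config$maf_min, miss_max = config$miss_max)
  else empty_assoc("lmm_wald")

  ## logistic mixed-model scan on the dichotomized trait ---------------
  y_bin <- dichotomize(y_raw)
  idx_glmm <- which(!is.na(y_bin))
  null_glmm <- fit_glmm_null(y_bin[idx_glmm], X_all[idx_glmm, , drop = FALSE],
                             kin$K[idx_glmm, idx_glmm])
  assoc_glmm <- glmm_gwas(null_glmm, subset_genotypes(G, samples = idx_glmm),
                          maf_min = config$maf_min, miss_max = config$miss_max)

  ## windowed SKAT on the untransformed trait --------------------------
  skat_X <- cbind(X_all, struct_cov)
  skat_res <- skat_scan(y_raw, skat_X, G, width = config$skat_width,
                        step = config$skat_step, beta_par = config$skat_beta,
                        maf_min = config$skat_maf_min,
                        p_gate = config$skat_gate,
                        sig_level = config$alpha / max(1L, nrow(make_windows(G,
                          config$skat_width, config$skat_step))),
                        B_max = config$skat_B_max, seed = config$seed,
                        workers = config$workers)

  ## ART ---------------------------------------------------------------
  genome_bp <- config$genome_bp
  if (is.null(genome_bp))
    genome_bp <- sum(vapply(unique(G$chrom),
                            function(ch) max(G$pos[G$chrom == ch]),
                            integer(1)))
  art_thr <- art_bonferroni_threshold(genome_bp, config$art_window_bp,
                                      config$alpha)
  audit$art_threshold <- art_thr
  audit$genome_bp <- genome_bp
  art_lmm <- art_apply(art_anchor_scan(assoc_lmm,
                                       anchor_p = config$anchor_p,
                                       neighbor_p = config$neighbor_p,
                                       neighbor_bp = config$neighbor_bp,
                                       min_neighbors = config$min_neighbors,
                                       window_bp = config$art_window_bp),
                       art_thr)
  wald_fun <- function(snp_id) {
    j <- match(snp_id, G$snp_ids)
    if (is.na(j)) return(NA_real_)
    row <- glmm_wald_refit(y_bin[idx_glmm], X_all[idx_glmm, , drop = FALSE],
                           kin$K[idx_glmm, idx_glmm],
                           G$dosages[idx_glmm, j])
    row$p
  }
  art_glmm <- art_two_round_gmmat(assoc_glmm, wald_fun, art_thr,
                                  anchor_p = config$anchor_p,
                                  neighbor_p = config$neighbor_p,
                                  neighbor_bp = config$neighbor_bp,
                                  min_neighbors = config$min_neighbors,
                                  window_bp = config$art_window_bp)

  ## tiers, peaks, genes -----------------------------------------------
  peak_tabs <- list()
  if (nrow(assoc_lmm)) {
    assoc_lmm$tier <- threshold_tiers(assoc_lmm$p, config$alpha, config$fdr_q)
    peak_tabs$lmm <- find_peaks(assoc_lmm, config$peak_radius)
  }
  if (nrow(assoc_glmm)) {
    assoc_glmm$tier <- threshold_tiers(assoc_glmm$p, config$alpha, config$fdr_q)
    peak_tabs$glmm <- find_peaks(assoc_glmm, config$peak_radius)
  }
  if (nrow(skat_res)) {
    skat_loci <- data.frame(chrom = skat_res$chrom,
                            pos = as.integer((skat_res$start + skat_res$end) %/% 2),
                            p = ifelse(is.na(skat_res$p_emp), skat_res$p_param,
                                       skat_res$p_emp),
                            test = "skat", stringsAsFactors = FALSE)
    skat_loci$tier <- threshold_tiers(skat_loci$p, config$alpha, config$fdr_q)
    peak_tabs$skat <- find_peaks(skat_loci, config$peak_radius)
  }
  art_tabs <- list(art_lmm = art_lmm, art_glmm = art_glmm$round2)
  for (nm in names(art_tabs)) {
    aw <- art_tabs[[nm]]
    if (!nrow(aw)) next
    loci <- data.frame(chrom = aw$chrom,
                       pos = as.integer((aw$start + aw$end) %/% 2),
                       p = aw$p_combined,
                       test = nm, stringsAsFactors = FALSE)
    loci$tier <- ifelse(!is.na(loci$p) & loci$p <= art_thr,
                        "ART-Bonferroni", "none")
    peak_tabs[[nm]] <- find_peaks(loci[!is.na(loci$p), , drop = FALSE],
                                  config$peak_radius)
  }
  peaks <- do.call(rbind, lapply(names(peak_tabs), function(nm) {
    pt <- peak_tabs[[nm]]
    if (!nrow(pt)) return(NULL)
    base <- data.frame(method = nm, chrom = pt$chrom, pos = pt$pos,
                       p = pt$p, tier = pt$tier, stringsAsFactors = FALSE)
    if (!is.null(annotation)) {
      gene <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i)
        assign_gene(pt$chrom[i], pt$pos[i], annotation, config$proximal_bp)))
      base <- cbind(base, gene)
    }
    base
  }))
  if (is.null(peaks))
    peaks <- data.frame(method = character(0), chrom = character(0),
                        pos = integer(0), p = numeric(0), tier = character(0),
                        within_5kb = logical(0))
  tier_summary <- summarize_tiers(peaks[peaks$tier != "none", , drop = FALSE])

  ## deterministic output ----------------------------------------------
  wtsv <- function(d, name) {
    d <- d[, !vapply(d, is.list, logical(1)), drop = FALSE]
    path <- file.path(outdir, name)
    con <- file(path, open = "wb")  # fixed EOLs for byte-identical reruns
    write.table(format(d, digits = 15, trim = TRUE, scientific = NA),
                con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    close(con)
    path
  }
  files <- c(
    wtsv(assoc_lmm, "assoc_lmm.tsv"),
    wtsv(assoc_glmm, "assoc_glmm.tsv"),
    wtsv(skat_res, "skat_windows.tsv"),
    wtsv(art_lmm, "art_lmm.tsv"),
    wtsv(art_glmm$round1, "art_glmm_round1.tsv"),
    wtsv(art_glmm$round2, "art_glmm_round2.tsv"),
    wtsv(peaks, "peaks.tsv"),
    wtsv(tier_summary, "tier_summary.tsv"))
  audit$n_assoc_lmm <- nrow(assoc_lmm)
  audit$n_assoc_glmm <- nrow(assoc_glmm)
  audit$n_skat_windows <- nrow(skat_res)
  audit$n_art_lmm <- nrow(art_lmm)
  audit$n_peaks <- nrow(peaks)
  jsonlite::write_json(audit, file.path(outdir, "audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assoc_lmm = assoc_lmm, assoc_glmm = assoc_glmm,
                 skat = skat_res, art_lmm = art_lmm, art_glmm = art_glmm,
                 peaks = peaks, tier_summary = tier_summary,
                 null_lmm = null_lmm, null_glmm = null_glmm,
                 files = files, audit = audit))
}
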