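#' Benjamini-Hochberg FDR flags
#'
#' Standard step-up adjustment via `stats::p.adjust`, with significance
#' flags at the study-wide FDR level (0.10 by default).
#'
#' @param p p-value vector.
#' @param q FDR level.
#' @return list with `adjusted` and logical `significant`.
#' @export
bh_fdr <- function(p, q = 0.10) {
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Deduplicate association signals into QTL peaks
#'
#' A tested locus is a peak iff no other locus within `radius` bp on the
#' same chromosome has a strictly smaller p-value; among equal-p
#' neighbors the leftmost position wins. The output is invariant to the
#' input row order.
#'
#' @param assoc data frame with `chrom`, `pos`, `p` (one row per tested
#'   locus; additional columns are carried through).
#' @param radius suppression radius in bp (default 30 kb).
#' @return the peak rows of `assoc`, ordered by chromosome and position.
#' @export
find_peaks <- function(assoc, radius = 30000L) {
  assoc <- assoc[!is.na(assoc$p), , drop = FALSE]
  if (nrow(assoc) == 0L) return(assoc)
  assoc <- assoc[order(assoc$chrom, assoc$pos), , drop = FALSE]
  keep <- logical(nrow(assoc))
  for (ch in unique(assoc$chrom)) {
    idx <- which(assoc$chrom == ch)
    pos <- assoc$pos[idx]; p <- assoc$p[idx]
    for (i in seq_along(idx)) {
      near <- which(abs(pos - pos[i]) <= radius)
      near <- near[near != i]
      beaten <- any(p[near] < p[i]) ||
        any(p[near] == p[i] & pos[near] < pos[i])
      keep[idx[i]] <- !beaten
    }
  }
  out <- assoc[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the nearest gene to a QTL peak
#'
#' A peak inside a gene body is assigned that gene, with relation
#' `exonic` or `intragenic-nonexonic` by exon overlap and TSS distance 0.
#' Otherwise the nearest gene by bp gap is chosen (equidistant flanking
#' genes tie-break to the nearer TSS, then leftmost), the relation is
#' `5'` or `3'` by strand-aware side, and the distance to the
#' transcription start site is reported. `within_5kb` flags a gap of at
#' most `proximal_bp` to the nearest gene boundary (zero when
#' intragenic).
#'
#' @param chrom,pos peak locus.
#' @param ann a `gene_annotation`.
#' @param proximal_bp proximity flag threshold (default 5 kb).
#' @return one-row data frame `gene_id, relation, tss_distance, gap_bp,
#'   within_5kb` (`gene_id` `NA` when the annotation has no gene on the
#'   chromosome).
#' @export
assign_gene <- function(chrom, pos, ann, proximal_bp = 5000L) {
  g <- ann$genes[ann$genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(gene_id = NA_character_, relation = NA_character_,
                      tss_distance = NA_real_, gap_bp = NA_real_,
                      within_5kb = NA, stringsAsFactors = FALSE))
  inside <- which(g$start <= pos & pos <= g$end)
  if (length(inside)) {
    gi <- g[inside[1L], ]
    ex <- ann$exons[ann$exons$gene_id == gi$gene_id, , drop = FALSE]
    in_exon <- nrow(ex) > 0L && any(ex$start <= pos & pos <= ex$end)
    return(data.frame(gene_id = gi$gene_id,
                      relation = if (in_exon) "exonic" else "intragenic-nonexonic",
                      tss_distance = 0, gap_bp = 0, within_5kb = TRUE,
                      stringsAsFactors = FALSE))
  }
  gap <- pmax(g$start - pos, pos - g$end)
  tss <- ifelse(g$strand == "-", g$end, g$start)
  best <- which(gap == min(gap))
  if (length(best) > 1L) {
    tgap <- abs(tss[best] - pos)
    best <- best[tgap == min(tgap)]
    if (length(best) > 1L) best <- best[which.min(g$start[best])]
  }
  gi <- g[best[1L], ]
  tss_i <- tss[best[1L]]
  upstream <- if (gi$strand == "-") pos > gi$end else pos < gi$start
  data.frame(gene_id = gi$gene_id,
             relation = if (upstream) "5'" else "3'",
             tss_distance = abs(pos - tss_i),
             gap_bp = gap[best[1L]],
             within_5kb = gap[best[1L]] <= proximal_bp,
             stringsAsFactors = FALSE)
}

#' Tally peaks by method, threshold tier and gene proximity
#'
#' @param peaks peak data frame with `method`, `tier`, `within_5kb`.
#' @return count data frame over `method x tier x within_5kb` (zero rows
#'   for an empty input).
#' @export
summarize_tiers <- function(peaks) {
  if (nrow(peaks) == 0L)
    return(data.frame(method = character(0), tier = character(0),
                      within_5kb = logical(0), n = integer(0)))
  tab <- aggregate(list(n = rep(1L, nrow(peaks))),
                   by = list(method = peaks$method, tier = peaks$tier,
                             within_5kb = peaks$within_5kb),
                   FUN = sum)
  tab[order(tab$method, tab$tier, tab$within_5kb), , drop = FALSE]
}

#' Threshold tier of each association
#'
#' Most to least conservative: `conservative-Bonferroni`
#' (`p <= alpha / n_tests`), `FDR-0.10` (BH-adjusted `p <= q`), else
#' `none`. Every conservative-Bonferroni call is by construction also an
#' FDR call at `q >= alpha / n_tests`-scale levels.
#'
#' @param p p-value vector (all tests, not only peaks).
#' @param alpha family-wise error rate.
#' @param q FDR level.
#' @return character vector of tiers aligned with `p`.
#' @export
threshold_tiers <- function(p, alpha = 0.05, q = 0.10) {
  thr <- conservative_bonferroni(length(p), alpha)
  fdr <- bh_fdr(p, q)
  ifelse(p <= thr, "conservative-Bonferroni",
         ifelse(fdr$significant, "FDR-0.10", "none"))
}
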