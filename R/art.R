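#' Scan single-SNP results for ART anchor windows
#'
#' A 1 kb window is emitted around every "anchor" SNP whose p-value falls
#' below `anchor_p` and which lies within `neighbor_bp` of at least
#' `min_neighbors` additional SNPs with p-values below `neighbor_p`.
#' The window is centred on the anchor and its member p-values are the
#' qualifying SNPs' (anchor plus neighbors), sorted.
#'
#' @param assoc association data frame (`chrom, pos, p`, one row per SNP).
#' @param anchor_p anchor threshold (default 1e-5).
#' @param neighbor_p neighbor threshold (default 1e-4).
#' @param neighbor_bp neighborhood half-width in bp (default 500).
#' @param min_neighbors distinct additional SNPs required (default 5).
#' @param window_bp emitted window width (default 1000).
#' @return data frame `chrom, start, end, anchor_pos, anchor_p, L, k` with
#'   list column `member_p` (sorted member p-values) and `member_pos`.
#' @export
art_anchor_scan <- function(assoc, anchor_p = 1e-5, neighbor_p = 1e-4,
                            neighbor_bp = 500L, min_neighbors = 5L,
                            window_bp = 1000L) {
  assoc <- assoc[!is.na(assoc$p), , drop = FALSE]
  out <- list(); k <- 1L
  for (ch in unique(assoc$chrom)) {
    a <- assoc[assoc$chrom == ch, , drop = FALSE]
    a <- a[order(a$pos), , drop = FALSE]
    anchors <- which(a$p < anchor_p)
    for (i in anchors) {
      near <- which(abs(a$pos - a$pos[i]) <= neighbor_bp)
      near <- setdiff(near, i)
      qual <- near[a$p[near] < neighbor_p]
      if (length(qual) < min_neighbors) next
      mem <- sort(c(i, qual))
      # tie-break ordering inside the window: p first, then position
      ord <- mem[order(a$p[mem], a$pos[mem])]
      L <- length(mem)
      out[[k]] <- list(chrom = ch,
                       start = a$pos[i] - window_bp %/% 2L,
                       end = a$pos[i] + window_bp %/% 2L - 1L,
                       anchor_pos = a$pos[i], anchor_p = a$p[i],
                       L = L, k_trunc = ceiling(L / 2),
                       member_p = a$p[ord], member_pos = a$pos[ord])
      k <- k + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), anchor_pos = integer(0),
                      anchor_p = numeric(0), L = integer(0),
                      k_trunc = integer(0)))
  df <- data.frame(chrom = vapply(out, `[[`, character(1), "chrom"),
                   start = vapply(out, function(x) as.integer(x$start), integer(1)),
                   end = vapply(out, function(x) as.integer(x$end), integer(1)),
                   anchor_pos = vapply(out, function(x) as.integer(x$anchor_pos),
                                       integer(1)),
                   anchor_p = vapply(out, `[[`, numeric(1), "anchor_p"),
                   L = vapply(out, function(x) as.integer(x$L), integer(1)),
                   k_trunc = vapply(out, function(x) as.integer(x$k_trunc),
                                    integer(1)),
                   stringsAsFactors = FALSE)
  df$member_p <- lapply(out, `[[`, "member_p")
  df$member_pos <- lapply(out, `[[`, "member_pos")
  df
}

#' Combine p-values by augmented rank truncation
#'
#' Combines the `k` smallest of `L` p-values. Conditional on the
#' `(k+1)`-th order statistic `p_(k+1)`, the `k` smallest are order
#' statistics of uniforms on `(0, p_(k+1))`, so
#' `sum_{i<=k} log(p_(k+1)/p_(i))` is Gamma(k, 1); the augmentation term
#' `-log F_Beta(k+1, L-k)(p_(k+1))` is an independent Exp(1). Their sum is
#' referred to a Gamma(k+1, 1) null and the upper-tail probability is the
#' combined p-value. With `L = 1` the combined p-value equals the input.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @param k truncation count; defaults to the upper half,
#'   `ceiling(length(p)/2)`.
#' @return combined p-value in `(0, 1]`.
#' @export
art_combine <- function(p, k = ceiling(length(p) / 2)) {
  if (length(p) == 0L) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  L <- length(p)
  if (L == 1L) return(p)
  k <- min(max(as.integer(k), 1L), L - 1L)
  ps <- sort(p)
  pk1 <- ps[k + 1L]
  core <- sum(log(pk1) - log(ps[seq_len(k)]))
  aug <- -log(pbeta(pk1, k + 1, L - k))
  stat <- core + aug
  pgamma(stat, shape = k + 1, rate = 1, lower.tail = FALSE)
}

#' ART Bonferroni threshold from genome size
#'
#' The number of independent tests is approximated by the contiguous
#' assembled genome size divided by the combination window size, and the
#' threshold is `alpha` over that count. For a 394 Mb genome and 1 kb
#' windows at `alpha = 0.05` this gives about 1.27e-7.
#'
#' @param genome_bp contiguous assembled genome size in bp.
#' @param window_bp combination window size in bp (default 1000).
#' @param alpha family-wise error rate (default 0.05).
#' @return significance threshold.
#' @export
art_bonferroni_threshold <- function(genome_bp, window_bp = 1000,
                                     alpha = 0.05) {
  if (genome_bp <= 0 || window_bp <= 0)
    stop("sizes must be positive", call. = FALSE)
  alpha / (genome_bp / window_bp)
}

#' Conservative Bonferroni threshold from the number of tests
#'
#' @param n_tests total number of tests (e.g. number of filtered SNPs).
#' @param alpha family-wise error rate (default 0.05).
#' @return significance threshold.
#' @export
conservative_bonferroni <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || n_tests < 1)
    stop("`n_tests` must be at least 1", call. = FALSE)
  alpha / n_tests
}

#' Apply ART to an anchor scan
#'
#' @param windows output of [art_anchor_scan()].
#' @param threshold significance threshold for `pass_threshold`
#'   (e.g. from [art_bonferroni_threshold()]); `NA` skips flagging.
#' @return `windows` with `p_combined` and `pass_threshold` columns.
#' @export
art_apply <- function(windows, threshold = NA_real_) {
  if (nrow(windows) == 0L) {
    windows$p_combined <- numeric(0)
    windows$pass_threshold <- logical(0)
    return(windows)
  }
  windows$p_combined <- vapply(seq_len(nrow(windows)), function(i)
    art_combine(windows$member_p[[i]], windows$k_trunc[i]), numeric(1))
  windows$pass_threshold <- if (is.na(threshold)) NA else
    windows$p_combined <= threshold
  windows
}

#' Two-round ART over logistic mixed-model results
#'
#' Round 1 applies ART to score-test p-values. For windows passing the
#' ART threshold, the member SNPs' p-values are recomputed with the more
#' accurate (and much slower) Wald refit, and ART is applied again to the
#' Wald p-values. Both rounds are returned.
#'
#' @param score_assoc association data frame from [glmm_gwas()].
#' @param wald_fun callback `function(snp_id) -> p-value` performing the
#'   Wald refit for one SNP (returns `NA` if unavailable).
#' @param threshold ART significance threshold.
#' @param ... forwarded to [art_anchor_scan()].
#' @return list with `round1` and `round2` window data frames; `round2`
#'   has an `incomplete` flag for windows with any failed Wald refit.
#' @export
art_two_round_gmmat <- function(score_assoc, wald_fun, threshold, ...) {
  r1 <- art_apply(art_anchor_scan(score_assoc, ...), threshold)
  hits <- which(r1$pass_threshold %in% TRUE)
  if (length(hits) == 0L) {
    r2 <- r1[0, , drop = FALSE]
    r2$incomplete <- logical(0)
    return(list(round1 = r1, round2 = r2))
  }
  r2 <- r1[hits, , drop = FALSE]
  r2$incomplete <- FALSE
  lookup <- paste(score_assoc$chrom, score_assoc$pos)
  for (i in seq_len(nrow(r2))) {
    pos <- r2$member_pos[[i]]
    ids <- score_assoc$snp_id[match(paste(r2$chrom[i], pos), lookup)]
    wp <- unname(vapply(ids, wald_fun, numeric(1)))
    if (any(is.na(wp))) {
      r2$incomplete[i] <- TRUE
      wp <- wp[!is.na(wp)]
    }
    if (length(wp) == 0L) {
      r2$p_combined[i] <- NA_real_
      r2$pass_threshold[i] <- NA
      next
    }
    r2$member_p[[i]] <- sort(wp)
    r2$L[i] <- length(wp)
    r2$k_trunc[i] <- ceiling(length(wp) / 2)
    r2$p_combined[i] <- art_combine(sort(wp), r2$k_trunc[i])
    r2$pass_threshold[i] <- r2$p_combined[i] <= threshold
  }
  list(round1 = r1, round2 = r2)
}
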