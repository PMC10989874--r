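#' Simulate a toy gene annotation
#'
#' Places non-overlapping genes with 1-3 exons along the chromosomes
#' spanned by `G`, for exercising peak-to-gene assignment. Intervals are
#' 1-based and closed, per GFF3 convention.
#'
#' @param G a [genotype_matrix()] defining chromosome extents.
#' @param n_genes total number of genes, split across chromosomes.
#' @param gene_length mean gene length in bp.
#' @param seed integer seed.
#' @return a `gene_annotation` list with data frames `genes`
#'   (`gene_id, chrom, start, end, strand`) and `exons`
#'   (`gene_id, chrom, start, end`).
#' @export
simulate_annotation <- function(G, n_genes = 20L, gene_length = 2000, seed = 1L) {
  set.seed(seed)
  chroms <- unique(G$chrom)
  per <- diff(round(seq(0, n_genes, length.out = length(chroms) + 1L)))
  genes <- list(); exons <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    span <- max(G$pos[G$chrom == ch])
    ng <- per[ci]
    if (ng == 0L) next
    # anchor genes on an even grid with jitter, keeping them disjoint
    anchors <- round(seq(1, span, length.out = ng + 2L))[2:(ng + 1L)]
    for (gi in seq_len(ng)) {
      len <- max(200L, round(rexp(1, 1 / gene_length)))
      start <- max(1L, anchors[gi] - len %/% 2L)
      end <- start + len - 1L
      id <- sprintf("gene_%s_%02d", ch, gi)
      strand <- sample(c("+", "-"), 1L)
      genes[[id]] <- data.frame(gene_id = id, chrom = ch, start = start,
                                end = end, strand = strand,
                                stringsAsFactors = FALSE)
      n_ex <- sample(1:3, 1L)
      cuts <- sort(sample(seq(start, end), 2L * n_ex))
      exons[[id]] <- data.frame(gene_id = id, chrom = ch,
                                start = cuts[seq(1L, by = 2L, length.out = n_ex)],
                                end = cuts[seq(2L, by = 2L, length.out = n_ex)],
                                stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes); rownames(genes) <- NULL
  exons <- do.call(rbind, exons); rownames(exons) <- NULL
  # clip overlaps produced by jitter: drop any gene overlapping its predecessor
  keep <- rep(TRUE, nrow(genes))
  for (ch in chroms) {
    idx <- which(genes$chrom == ch)
    if (length(idx) > 1L)
      for (k in 2:length(idx))
        if (genes$start[idx[k]] <= genes$end[idx[k - 1L]]) keep[idx[k]] <- FALSE
  }
  exons <- exons[exons$gene_id %in% genes$gene_id[keep], ]
  structure(list(genes = genes[keep, ], exons = exons),
            class = "gene_annotation")
}

#' Write genotypes as a VCF 4.2 file
#'
#' Emits biallelic SNPs with a GT field encoding dosages 0/1/2 as
#' `0/0`, `0/1`, `1/1` (missing as `./.`). Alleles are placeholders
#' (REF=A, ALT=T); the round-trip contract covers dosages and coordinates.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=regenmap",
           sprintf("##contig=<ID=%s,length=%d>", unique(G$chrom),
                   vapply(unique(G$chrom),
                          function(ch) max(G$pos[G$chrom == ch]) + 1000L,
                          integer(1))),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  gt <- matrix(gt_code[as.character(G$dosages)], nrow = nrow(G$dosages))
  gt[is.na(G$dosages)] <- "./."
  body <- paste(G$chrom, G$pos, G$snp_ids, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses `vcfR` for parsing; genotypes are converted to 0/1/2 dosages by
#' counting ALT alleles, with unphased and phased separators accepted.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  clean <- gsub("\\|", "/", gt)
  dos_t <- matrix(c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)[clean],
                  nrow = nrow(gt))
  dos <- t(dos_t)
  fix <- vcfR::getFIX(v)
  genotype_matrix(dos, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  sample_ids = colnames(gt), snp_ids = fix[, "ID"])
}

#' Write a gene annotation as GFF3
#'
#' @param ann a `gene_annotation` (see [simulate_annotation()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes
  gene_lines <- sprintf("%s\tregenmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        g$chrom, g$start, g$end, g$strand, g$gene_id)
  ex_lines <- character(0)
  if (!is.null(ann$exons) && nrow(ann$exons)) {
    e <- ann$exons
    strand <- g$strand[match(e$gene_id, g$gene_id)]
    ex_lines <- sprintf("%s\tregenmap\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon;Parent=%s",
                        e$chrom, e$start, e$end, strand,
                        make.unique(e$gene_id), e$gene_id)
  }
  writeLines(c("##gff-version 3", gene_lines, ex_lines), path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses with `rtracklayer` and returns the same `gene_annotation` shape
#' the simulator produces, so synthetic and real annotations are
#' interchangeable downstream.
#'
#' @param path a GFF3 file containing `gene` (and optionally `exon`) features.
#' @return a `gene_annotation` list.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  ex <- df[df$type == "exon", ]
  parent <- if (nrow(ex) && "Parent" %in% names(ex))
    vapply(ex$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  else rep(NA_character_, nrow(ex))
  structure(list(
    genes = data.frame(gene_id = as.character(genes$ID),
                       chrom = as.character(genes$seqnames),
                       start = genes$start, end = genes$end,
                       strand = as.character(genes$strand),
                       stringsAsFactors = FALSE),
    exons = if (nrow(ex)) data.frame(gene_id = parent,
                                     chrom = as.character(ex$seqnames),
                                     start = ex$start, end = ex$end,
                                     stringsAsFactors = FALSE)
            else data.frame(gene_id = character(0), chrom = character(0),
                            start = integer(0), end = integer(0))
  ), class = "gene_annotation")
}

#' Trait table CSV round trip
#'
#' @param traits a trait table data frame.
#' @param path file path.
#' @return `path` invisibly / the trait table.
#' @export
write_traits_csv <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("phase" %in% names(out)) out$phase <- factor(out$phase)
  out
}

#' Read an ancestry-fraction (Q model) matrix
#'
#' Tab-separated, rows = samples, columns = ancestry fractions that sum to
#' one per row; an optional first column of sample IDs is detected.
#'
#' @param path TSV file.
#' @return numeric matrix of ancestry fractions (rows sum to 1).
#' @export
read_qmatrix <- function(path) {
  q <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  ids <- NULL
  if (is.character(q[[1]])) { ids <- q[[1]]; q <- q[, -1, drop = FALSE] }
  q <- as.matrix(q)
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop("ancestry fractions must sum to 1 per sample", call. = FALSE)
  rownames(q) <- ids
  q
}

#' Kinship matrix TSV round trip
#'
#' Square matrix with a sample-ID header row and column.
#'
#' @param K kinship object (see [compute_grm()]) or square matrix.
#' @param path file path.
#' @return `path` invisibly / a numeric matrix.
#' @export
write_kinship_tsv <- function(K, path) {
  M <- if (inherits(K, "kinship")) K$K else as.matrix(K)
  utils::write.table(data.frame(sample = rownames(M), M, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  M <- as.matrix(d[, -1])
  rownames(M) <- d[[1]]
  M
}

#' Segmentation mask PNG round trip
#'
#' Masks are stored as 8-bit single-channel PNGs with the raw class labels
#' (0 background, 1 stem, 2 callus, 3 shoot) as pixel values.
#'
#' @param mask integer label matrix.
#' @param path file path.
#' @return `path` invisibly / an integer label matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  structure(matrix(as.integer(round(img * 255)), nrow = nrow(img)),
            class = c("segmentation_mask", "matrix", "array"))
}
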