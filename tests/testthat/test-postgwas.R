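test_that("BH step-up matches the hand-computed oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.10)
  expect_equal(out$adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_identical(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_equal(bh_fdr(0.05)$adjusted, 0.05)
})

test_that("the 30 kb rule keeps only locally most significant loci", {
  a <- data.frame(chrom = "chr01", pos = c(100000L, 110000L),
                  p = c(1e-9, 1e-7))
  expect_identical(find_peaks(a)$pos, 100000L)

  b <- data.frame(chrom = "chr01", pos = c(100000L, 140000L),
                  p = c(1e-9, 1e-7))
  expect_identical(find_peaks(b)$pos, c(100000L, 140000L))

  tie <- data.frame(chrom = "chr01", pos = c(110000L, 100000L),
                    p = c(1e-8, 1e-8))
  expect_identical(find_peaks(tie)$pos, 100000L)  # leftmost wins

  # invariance to input ordering
  set.seed(14)
  big <- data.frame(chrom = sample(c("chr01", "chr02"), 60, TRUE),
                    pos = sample.int(2e5, 60), p = runif(60))
  shuf <- big[sample.int(60), ]
  expect_identical(find_peaks(big), find_peaks(shuf))
})

test_that("gene assignment covers intragenic, flanking and tie cases", {
  ann <- structure(list(
    genes = data.frame(
      gene_id = c("gA", "gB", "gC"),
      chrom = "chr01",
      start = c(1000L, 8000L, 20000L),
      end = c(2000L, 9000L, 21000L),
      strand = c("+", "-", "+"),
      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gA", "gA"), chrom = "chr01",
                       start = c(1000L, 1800L), end = c(1200L, 2000L),
                       stringsAsFactors = FALSE)),
    class = "gene_annotation")

  up3 <- assign_gene("chr01", 997L, ann)  # 3 bp upstream of a + strand TSS
  expect_identical(up3$gene_id, "gA")
  expect_identical(up3$relation, "5'")
  expect_equal(up3$tss_distance, 3)
  expect_true(up3$within_5kb)

  ex <- assign_gene("chr01", 1100L, ann)  # inside an exon
  expect_identical(ex$relation, "exonic")
  expect_equal(ex$tss_distance, 0)

  intron <- assign_gene("chr01", 1500L, ann)
  expect_identical(intron$relation, "intragenic-nonexonic")

  # 9200 is 200 bp past gB's end; gB is on the minus strand so its TSS is
  # the end coordinate and the locus sits 5' of the gene
  minus_side <- assign_gene("chr01", 9200L, ann)
  expect_identical(minus_side$gene_id, "gB")
  expect_identical(minus_side$relation, "5'")
  expect_equal(minus_side$tss_distance, 200)

  # equidistant between gB (end 9000) and a hypothetical; construct exact tie
  ann_tie <- ann
  ann_tie$genes$start[3] <- 9400L
  ann_tie$genes$end[3] <- 9600L
  tie <- assign_gene("chr01", 9200L, ann_tie)  # 200 bp from both
  # gC (+) TSS at 9400 is 200 away; gB (-) TSS at 9000 is 200 away: tss tie
  # -> leftmost gene (gB) wins
  expect_identical(tie$gene_id, "gB")

  far <- assign_gene("chr01", 14400L, ann)
  expect_false(far$within_5kb)

  empty <- assign_gene("chr09", 100L, ann)
  expect_true(is.na(empty$gene_id))
})

test_that("tier assignment is monotone and tallies reproduce a fixture", {
  set.seed(15)
  p <- c(1e-10, 1e-4, 2e-4, runif(96, 0.2, 1))
  tiers <- threshold_tiers(p, alpha = 0.05, q = 0.10)
  expect_identical(tiers[1], "conservative-Bonferroni")
  # every conservative call would also pass FDR
  fdr <- bh_fdr(p, 0.10)
  expect_true(all(fdr$significant[tiers == "conservative-Bonferroni"]))

  peaks <- data.frame(
    method = c("lmm", "lmm", "glmm"),
    tier = c("conservative-Bonferroni", "FDR-0.10", "FDR-0.10"),
    within_5kb = c(TRUE, FALSE, TRUE))
  tab <- summarize_tiers(peaks)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$n, rep(1L, 3))
  empty <- summarize_tiers(peaks[0, ])
  expect_identical(nrow(empty), 0L)
})
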