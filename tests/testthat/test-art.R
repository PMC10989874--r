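# Monte-Carlo oracle for the combined p-value: the null distribution of the
# combining statistic simulated directly from independent uniforms.
art_mc_null <- function(L, k, n_rep, seed) {
  set.seed(seed)
  replicate(n_rep, {
    ps <- sort(runif(L))
    sum(log(ps[k + 1]) - log(ps[seq_len(k)])) -
      log(pbeta(ps[k + 1], k + 1, L - k))
  })
}

test_that("anchor scanning applies the exact neighborhood criteria", {
  mk <- function(pos, p) data.frame(chrom = "chr01", pos = pos, p = p)
  # anchor at 1e-6 with 5 qualifying neighbors within 500 bp -> emitted
  a5 <- mk(c(1000, 700, 800, 1200, 1300, 1450, 5000),
           c(1e-6, 5e-5, 5e-5, 5e-5, 5e-5, 5e-5, 0.5))
  win <- art_anchor_scan(a5)
  expect_identical(nrow(win), 1L)
  expect_identical(win$anchor_pos, 1000L)
  expect_identical(win$L, 6L)
  expect_identical(win$k_trunc, 3L)
  # only 4 qualifying neighbors -> not emitted
  a4 <- mk(c(1000, 700, 800, 1200, 1300), c(1e-6, 5e-5, 5e-5, 5e-5, 5e-5))
  expect_identical(nrow(art_anchor_scan(a4)), 0L)
  # a neighbor at exactly 501 bp is outside the window
  a501 <- mk(c(1000, 1501, 800, 1200, 1300, 1450),
             c(1e-6, 5e-5, 5e-5, 5e-5, 5e-5, 5e-5))
  expect_identical(nrow(art_anchor_scan(a501)), 0L)
  # ... while exactly 500 bp is inside
  a500 <- mk(c(1000, 1500, 800, 1200, 1300, 1450),
             c(1e-6, 5e-5, 5e-5, 5e-5, 5e-5, 5e-5))
  expect_identical(nrow(art_anchor_scan(a500)), 1L)
  # neighbors must beat the neighbor threshold, anchors the anchor threshold
  weak <- mk(c(1000, 700, 800, 1200, 1300, 1450),
             c(2e-5, 5e-5, 5e-5, 5e-5, 5e-5, 5e-5))
  expect_identical(nrow(art_anchor_scan(weak)), 0L)
})

test_that("combining a single p-value is the identity", {
  for (p in c(1e-8, 0.037, 0.5, 1))
    expect_identical(art_combine(p), p)
  expect_error(art_combine(c(0.2, 0)), "0, 1")
  expect_error(art_combine(c(0.2, 1.4)), "0, 1")
  expect_error(art_combine(numeric(0)), "no p-values")
})

test_that("combined p-values are uniform under the null (MC calibration)", {
  for (L in c(2L, 6L, 10L)) {
    k <- ceiling(L / 2)
    set.seed(100 + L)
    ps <- vapply(seq_len(3000L), function(i) art_combine(runif(L)),
                 numeric(1))
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
    # and the closed form matches the simulated null distribution
    null_stats <- art_mc_null(L, k, 3000L, seed = 200 + L)
    obs_stat <- qgamma(0.01, shape = k + 1, lower.tail = FALSE)
    expect_lt(abs(mean(null_stats > obs_stat) - 0.01), 0.007)
  }
})

test_that("concordant small p-values combine to stronger evidence", {
  p10 <- rep(1e-4, 10)
  expect_lt(art_combine(p10), 1e-4)
})

test_that("decreasing a member p-value never weakens the combination", {
  set.seed(30)
  for (i in seq_len(200L)) {
    L <- sample(2:10, 1L)
    p <- runif(L, min = 1e-6, max = 0.2)
    j <- sample(L, 1L)
    p2 <- p
    p2[j] <- p[j] * runif(1)
    expect_lte(art_combine(p2), art_combine(p) + 1e-12)
  }
})

test_that("threshold arithmetic follows the independent-test counts", {
  expect_equal(art_bonferroni_threshold(1e6, 1000, 0.05), 5e-5)
  expect_equal(art_bonferroni_threshold(5e6, 5e6, 0.05), 0.05)
  expect_error(art_bonferroni_threshold(0), "positive")
  expect_equal(conservative_bonferroni(1), 0.05)
  expect_error(conservative_bonferroni(0), "at least 1")
})

test_that("two-round combination refits members and flags incomplete windows", {
  mk <- function(pos, p) data.frame(snp_id = sprintf("s%d", seq_along(pos)),
                                    chrom = "chr01", pos = pos, p = p)
  # no round-1 hits: round 2 vacuous
  none <- mk(c(1000, 5000), c(0.5, 0.2))
  out0 <- art_two_round_gmmat(none, function(id) 0.5, threshold = 1e-4)
  expect_identical(nrow(out0$round1), 0L)
  expect_identical(nrow(out0$round2), 0L)

  # every SNP is below the anchor threshold; the 1000 bp and 1200 bp loci
  # both have >= 5 qualifying neighbors within 500 bp, so two windows emit
  strong <- mk(c(1000, 700, 800, 1200, 1300, 1450),
               rep(c(1e-9, 1e-8), c(1, 5)))
  out1 <- art_two_round_gmmat(strong, function(id) 1e-7, threshold = 1e-4)
  expect_identical(nrow(out1$round2), 2L)
  expect_false(any(out1$round2$incomplete))
  expect_equal(out1$round2$member_p[[1]], rep(1e-7, 6))
  expect_true(all(out1$round2$p_combined <= 1e-4))

  out2 <- art_two_round_gmmat(strong,
                              function(id) if (id == "s3") NA_real_ else 1e-7,
                              threshold = 1e-4)
  expect_true(out2$round2$incomplete[1])
  expect_identical(out2$round2$L[1], 5L)
})
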