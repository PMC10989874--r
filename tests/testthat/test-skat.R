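test_that("staggered windows tile chromosomes as specified", {
  G <- list(chrom = rep("chr01", 3), pos = c(500L, 1500L, 3500L))
  win <- make_windows(G, width = 3000L, step = 1000L)
  w1 <- win[win$start == 1L, ]
  expect_identical(w1$snps[[1]], c(1L, 2L))
  w2 <- win[win$start == 1001L, ]
  expect_identical(w2$snps[[1]], c(2L, 3L))
  expect_true(all(win$n_snps >= 1L))

  disjoint <- make_windows(G, width = 1000L, step = 1000L)
  mem <- unlist(disjoint$snps)
  expect_identical(sort(mem), 1:3)  # each SNP in exactly one window

  empty <- make_windows(list(chrom = character(0), pos = integer(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("the kernel statistic matches its algebraic and brute-force forms", {
  set.seed(9)
  n <- 20L
  r <- rnorm(n)
  g <- rbinom(n, 2L, 0.3)
  w1 <- 2.5
  expect_equal(skat_stat(r, matrix(g), w1), w1^2 * sum(g * r)^2,
               tolerance = 1e-12)

  Gw <- matrix(rbinom(n * 5L, 2L, 0.3), n, 5L)
  w <- runif(5, 0.5, 2)
  Kmat <- Gw %*% diag(w^2) %*% t(Gw)  # dense brute force
  expect_lt(abs(skat_stat(r, Gw, w) - drop(t(r) %*% Kmat %*% r)), 1e-10)

  r_orth <- qr.resid(qr(Gw), r)  # residuals orthogonal to every member SNP
  expect_lt(skat_stat(r_orth, Gw, w), 1e-18)
})

test_that("weighted chi-square tails invert correctly", {
  # single component: exact closed form
  for (q in c(0.5, 3, 10)) {
    p <- pwchisq(q, lambda = 2)
    expect_equal(as.numeric(p), pchisq(q / 2, df = 1, lower.tail = FALSE),
                 tolerance = 1e-7)
    expect_identical(attr(p, "method"), "exact")
  }
  # two near-equal components: inversion, not moment matching
  p2 <- pwchisq(4, c(1, 0.8))
  expect_identical(attr(p2, "method"), "imhof")
  # several components: agreement with a Monte-Carlo oracle
  lam <- c(3, 1.5, 0.5, 0.2)
  set.seed(10)
  draws <- colSums(lam * matrix(rchisq(4 * 2e5, df = 1), 4))
  for (q in c(5, 12)) {
    mc <- mean(draws > q)
    expect_lt(abs(as.numeric(pwchisq(q, lam)) - mc), 3 * sqrt(mc / 2e5) + 1e-4)
  }
})

test_that("parametric SKAT p-values are uniform under the Gaussian null", {
  set.seed(11)
  n <- 60L
  X <- cbind(1, rnorm(n))
  ps <- vapply(seq_len(400L), function(i) {
    y <- rnorm(n)
    null <- skat_null(y, X)
    Gw <- matrix(rbinom(n * 6L, 2L, runif(1, 0.1, 0.5)), n, 6L)
    w <- skat_weights(colMeans(Gw) / 2)
    as.numeric(skat_pvalue(skat_stat(null$r, Gw, w), Gw, w, null))
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the statistic ignores covariate-spanned components of the trait", {
  set.seed(12)
  n <- 50L
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  Gw <- matrix(rbinom(n * 4L, 2L, 0.3), n, 4L)
  w <- rep(1, 4)
  q1 <- skat_stat(skat_null(y, X)$r, Gw, w)
  q2 <- skat_stat(skat_null(y + drop(X %*% c(3, -2)), X)$r, Gw, w)
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("empirical p-values follow the add-one formula and the stage logic", {
  set.seed(13)
  n <- 40L
  r <- rnorm(n)
  Gw <- matrix(rbinom(n * 3L, 2L, 0.4), n, 3L)
  w <- rep(1, 3)
  # an unreachable observed statistic: b = 0 after the first stage
  emp <- skat_empirical(r, Gw, w, Q_obs = Inf, sig_level = 0.5,
                        B_max = 999, stages = 999, seed = 3L)
  expect_equal(emp$p_emp, 1 / 1000)
  expect_identical(emp$B, 999L)
  expect_true(emp$converged)
  # a typical statistic agrees with its parametric p within MC error
  null <- skat_null(rnorm(n), matrix(1, n, 1))
  Q <- skat_stat(null$r, Gw, w)
  p_par <- as.numeric(skat_pvalue(Q, Gw, w, null))
  emp2 <- skat_empirical(null$r, Gw, w, Q, sig_level = 1e-6,
                         B_max = 2000, stages = 2000, seed = 5L)
  expect_gt(emp2$p_emp / p_par, 0.5)
  expect_lt(emp2$p_emp / p_par, 2)
})

test_that("window scans are bit-identical across worker counts", {
  fx <- small_pop()
  G <- fx$G
  m <- merge_replicates(fx$traits)
  sel <- m[m$timepoint == 4, ]
  y <- sel$callus_area[match(G$sample_ids, sel$genotype_id)]
  X <- matrix(1, length(y), 1)
  s1 <- skat_scan(y, X, G, p_gate = 0.5, B_max = 500, stages = 500,
                  sig_level = 1e-4, seed = 99L, workers = 1L)
  s4 <- skat_scan(y, X, G, p_gate = 0.5, B_max = 500, stages = 500,
                  sig_level = 1e-4, seed = 99L, workers = 4L)
  expect_identical(s1, s4)
  expect_true(all(s1$p_emp[!is.na(s1$p_emp)] >= 1 / 501))
  expect_true(all(s1$Q >= 0))
})
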