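# fixture: small regression problem with identity kinship
make_iid_problem <- function(n = 80L, seed = 101L) {
  set.seed(seed)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n)
  g <- rbinom(n, 2L, 0.3)
  list(y = y, X = X, g = g, K = diag(n))
}

test_that("with identity kinship the Wald test collapses to the OLS t-test", {
  pr <- make_iid_problem()
  null <- fit_lmm_null(pr$y, pr$X, pr$K)
  row <- lmm_snp_test(null, pr$g)
  ols <- summary(lm(pr$y ~ pr$X[, 2] + pr$g))$coefficients["pr$g", ]
  expect_lt(abs(row$p - ols["Pr(>|t|)"]), 1e-6)
  expect_equal(row$beta, unname(ols["Estimate"]), tolerance = 1e-8)
})

test_that("heritability is scale invariant and near zero for iid noise", {
  # a clearly structured relatedness matrix, so the REML surface is
  # informative about the (absent) polygenic component
  cfg <- sim_config(n_samples = 250L, n_snps = 2000L, n_subpops = 4L,
                    fst = 0.25, seed = 3L)
  K <- compute_grm(simulate_genotypes(cfg))$K
  set.seed(99)
  X <- cbind(1, rnorm(250))
  h2s <- vapply(1:3, function(s) {
    set.seed(s)
    y <- drop(X %*% c(1, 0.5)) + rnorm(250)
    fit_lmm_null(y, X, K)$h2
  }, numeric(1))
  expect_lt(mean(h2s), 0.05)  # no polygenic term was simulated
  set.seed(1)
  y <- drop(X %*% c(1, 0.5)) + rnorm(250)
  f1 <- fit_lmm_null(y, X, K)
  f10 <- fit_lmm_null(10 * y, X, K)
  expect_lt(abs(f1$h2 - f10$h2), 1e-8)
})

test_that("null-fit validation catches rank deficiency and asymmetry", {
  pr <- make_iid_problem()
  X_bad <- cbind(pr$X, dupcol = pr$X[, 2])
  expect_error(fit_lmm_null(pr$y, X_bad, pr$K), "dupcol")
  K_asym <- pr$K; K_asym[1, 2] <- 0.5
  expect_error(fit_lmm_null(pr$y, pr$X, K_asym), "symmetric")
  K_neg <- pr$K; K_neg[1, 1] <- -2
  expect_error(fit_lmm_null(pr$y, pr$X, K_neg), "positive semi-definite")
  expect_error(fit_lmm_null(pr$y[1:10], pr$X[1:10, ], pr$K[1:10, 1:10]),
               "at least 30")
})

test_that("monomorphic SNPs are skipped with a reason", {
  pr <- make_iid_problem()
  null <- fit_lmm_null(pr$y, pr$X, pr$K)
  row <- lmm_snp_test(null, rep(2, length(pr$y)))
  expect_identical(row$note, "monomorphic")
  expect_true(is.na(row$p))
})

test_that("allele recoding flips the sign of the effect but not the p-value", {
  pr <- make_iid_problem()
  null <- fit_lmm_null(pr$y, pr$X, pr$K)
  a <- lmm_snp_test(null, pr$g)
  b <- lmm_snp_test(null, 2 - pr$g)
  expect_equal(a$beta, -b$beta, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("the genome scan matches the single-SNP routine and applies filters", {
  fx <- small_pop()
  G <- fx$G
  m <- merge_replicates(fx$traits)
  sel <- m[m$timepoint == 4, ]
  y <- sel$callus_area[match(G$sample_ids, sel$genotype_id)]
  names(y) <- G$sample_ids
  tr <- transform_trait(y, "rbinv", outlier_z = Inf)
  X <- matrix(1, length(tr$kept), 1)
  K <- compute_grm(G)$K[tr$kept, tr$kept]
  null <- fit_lmm_null(unname(tr$values), X, K)
  Gs <- subset_genotypes(G, samples = tr$kept)
  scan <- lmm_gwas(null, Gs, maf_min = 0.05, miss_max = 0.1)
  expect_true(all(scan$maf >= 0.05))
  j <- match(scan$snp_id[5], Gs$snp_ids)
  single <- lmm_snp_test(null, Gs$dosages[, j])
  expect_equal(scan$p[5], single$p, tolerance = 1e-10)
  expect_equal(scan$beta[5], single$beta, tolerance = 1e-10)
})

test_that("structure correction keeps null tests calibrated where naive OLS inflates", {
  cfg <- sim_config(n_samples = 250L, n_snps = 1200L, n_subpops = 4L,
                    fst = 0.2, h2_poly = 0.5, zero_threshold = -Inf,
                    covariate_effects = list(diameter = 0, phase = rep(0, 4)),
                    timepoint_offsets = rep(0, 4), n_replicates = 1L,
                    seed = 77L)
  G <- simulate_genotypes(cfg)
  tr <- simulate_traits(G, cfg)
  y <- tr$callus_area[tr$timepoint == 4]
  X <- matrix(1, length(y), 1)
  K <- compute_grm(G)$K
  null <- fit_lmm_null(y, X, K)
  corrected <- lmm_gwas(null, G)
  lam_c <- lambda_gc(corrected$p)
  # naive per-SNP OLS with no relatedness adjustment
  p_naive <- apply(G$dosages[, snp_maf(G) >= 0.05], 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (sd(g) == 0) return(NA_real_)
    summary(lm(y ~ g))$coefficients[2, 4]
  })
  lam_n <- lambda_gc(p_naive)
  expect_gt(lam_c, 0.85)
  expect_lt(lam_c, 1.15)
  expect_gt(lam_n, 1.2)
})
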