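test_that("zero removal keeps strictly positive values and their indices", {
  dz <- drop_zeros(c(0, 0.1, 0.3, 0))
  expect_equal(dz$values, c(0.1, 0.3))
  expect_equal(dz$kept, c(2L, 3L))
  expect_warning(dz0 <- drop_zeros(c(0, 0)), "nothing retained")
  expect_length(dz0$values, 0L)
  x <- c(0.5, 1, 2)
  expect_equal(drop_zeros(x)$values, x)
})

test_that("Box-Cox MLE agrees with an independent grid-search oracle", {
  set.seed(1)
  x_norm <- rnorm(500, mean = 10, sd = 1)
  fit <- boxcox_mle(x_norm)
  expect_lt(abs(fit$lambda - 1), 0.5)
  # MASS profile over the same grid as the independent route
  or <- MASS::boxcox(v ~ 1, data = data.frame(v = x_norm),
                     lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(fit$lambda - or$x[which.max(or$y)]), 0.02)

  x_ln <- exp(rnorm(500))
  fit_ln <- boxcox_mle(x_ln)
  expect_lt(abs(fit_ln$lambda), 0.25)
  or_ln <- MASS::boxcox(v ~ 1, data = data.frame(v = x_ln),
                        lambda = seq(-2, 2, 0.01), plotit = FALSE)
  expect_lt(abs(fit_ln$lambda - or_ln$x[which.max(or_ln$y)]), 0.02)

  expect_equal(boxcox_apply(x_norm, 1), x_norm - 1)
  expect_error(boxcox_mle(rep(2, 50)), "degenerate")
  expect_error(boxcox_mle(c(-1, rep(2, 20))), "positive")
})

test_that("rank inverse-normal matches the normal-quantile oracle", {
  z <- rank_inverse_normal(c(5, 1, 9))
  # Blom scores for n = 3, frozen from qnorm((r - 3/8) / (n + 1/4))
  expect_equal(z, qnorm((c(2, 1, 3) - 0.375) / 3.25), tolerance = 1e-12)
  expect_equal(z[2], -z[3], tolerance = 1e-12)

  x <- c(-3, -1, 0, 1, 3)  # symmetric input -> antisymmetric scores
  zs <- rank_inverse_normal(x)
  expect_equal(zs, -rev(zs), tolerance = 1e-12)

  set.seed(2)
  heavy <- rt(200, df = 2)
  zt <- rank_inverse_normal(heavy)
  expect_gt(shapiro.test(zt)$p.value, 0.01)

  with_na <- rank_inverse_normal(c(1, NA, 2))
  expect_true(is.na(with_na[2]))
  expect_equal(with_na[c(1, 3)], rank_inverse_normal(c(1, 2)))
})

test_that("elbow rule separates a low spike from the main mass and knows when not to", {
  set.seed(3)
  x <- c(rnorm(800, 0, 0.05), rnorm(200, 1, 0.1))
  el <- elbow_threshold(x)
  expect_true(el$apply)
  # the cutoff lies between the spike mode (0) and the main mode (1), on
  # the decaying flank of the spike, and never cuts into the main mass
  expect_gt(el$cutoff, 0)
  expect_lt(el$cutoff, 0.8)
  expect_gt(el$n_below, 600)          # most of the spike goes
  expect_identical(sum(x > 0.5 & x < el$cutoff), 0L)  # main mass untouched

  # translation equivariance (same bandwidth rule, shifted grid)
  el_shift <- elbow_threshold(x + 10)
  expect_equal(el_shift$cutoff, el$cutoff + 10, tolerance = 1e-6)

  set.seed(4)
  uni <- rnorm(500)
  el_uni <- suppressWarnings(elbow_threshold(uni))
  if (!el_uni$apply) expect_true(is.na(el_uni$cutoff) ||
                                   el_uni$cutoff < quantile(uni, 0.01))
  expect_error(elbow_threshold(rnorm(10)), "at least 50")
})

test_that("normality diagnostics behave on normal and heavy-tailed input", {
  x <- qnorm(ppoints(100), mean = 3, sd = 2)
  rep_ <- normality_report(x)
  expect_gt(rep_$r_normal, 0.999)

  set.seed(5)
  heavy <- rt(300, df = 2)
  r_raw <- normality_report(heavy)$r_normal
  r_inv <- normality_report(rank_inverse_normal(heavy))$r_normal
  expect_gt(r_inv, r_raw)
  expect_error(normality_report(c(1, 2)), "at least 3")
})

test_that("dichotomization maps zeros to 0 and positives to 1", {
  expect_identical(dichotomize(c(0, 0.2, 0)), c(0L, 1L, 0L))
  expect_identical(dichotomize(c(1e-13, 0.5)), c(0L, 1L))
  expect_warning(dichotomize(c(0.1, 0.2)), "no variation")
  expect_true(is.na(dichotomize(c(NA, 1, 0))[1]))
})

test_that("trait PCA removes degenerate genotypes and returns orthonormal loadings", {
  set.seed(6)
  base <- runif(40)
  two <- cbind(t1 = base, t2 = 2 * base)  # perfectly correlated pair
  rownames(two) <- sprintf("g%02d", 1:40)
  pca2 <- trait_pca(two)
  expect_equal(pca2$variance_explained[1], 1, tolerance = 1e-12)

  rising <- sapply(1:4, function(t) base * t + rnorm(40, sd = 0.01))
  rownames(rising) <- rownames(two)
  pca4 <- trait_pca(rising)
  expect_lt(max(abs(crossprod(pca4$loadings) - diag(4))), 1e-8)
  expect_true(all(sign(pca4$loadings[, 1]) == sign(pca4$loadings[1, 1])))

  withzero <- rising
  withzero[1:3, ] <- 0
  withzero[4, 2] <- NA
  pz <- trait_pca(withzero)
  expect_equal(pz$n_dropped_allzero, 3L)
  expect_equal(pz$n_dropped_missing, 1L)
  expect_false(any(c("g01", "g04") %in% pz$included_genotypes))
})

test_that("transform recipes are rank-preserving and audit counts add up", {
  set.seed(7)
  x <- c(rep(0, 30), rlnorm(120))
  names(x) <- sprintf("g%03d", seq_along(x))
  for (method in c("boxcox", "rbinv")) {
    tr <- transform_trait(x, method = method, outlier_z = Inf)
    raw <- x[tr$kept]
    expect_equal(cor(rank(raw), rank(tr$values)), 1)
    expect_equal(tr$audit$n_input - tr$audit$n_missing - tr$audit$n_zero,
                 tr$audit$n_final)
    expect_identical(names(tr$values), names(x)[tr$kept])
  }
  tr_out <- transform_trait(x, method = "boxcox", outlier_z = 2)
  expect_equal(tr_out$audit$n_input - tr_out$audit$n_zero -
                 tr_out$audit$n_outlier, tr_out$audit$n_final)
})
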