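# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# modest structured population reused across read-only tests
small_pop <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- sim_config(n_samples = 150L, n_snps = 500L, n_subpops = 3L,
                      fst = 0.15, h2_poly = 0.3, seed = 42L)
    G <- simulate_genotypes(cfg)
    fixture_env$small <- list(cfg = cfg, G = G,
                              traits = simulate_traits(G, cfg))
  }
  fixture_env$small
}

# hand-built mask from class counts, raster order
mask_from_counts <- function(n_bg, n_stem, n_callus, n_shoot) {
  lab <- c(rep(0L, n_bg), rep(1L, n_stem), rep(2L, n_callus), rep(3L, n_shoot))
  n <- length(lab)
  nr <- floor(sqrt(n))
  while (n %% nr != 0L) nr <- nr - 1L
  matrix(lab, nrow = nr)
}

# textbook Hudson Fst estimator (ratio of averages over SNPs) from
# per-subpopulation allele counts; the independent oracle for the
# Balding-Nichols generator
hudson_fst <- function(G) {
  pops <- unique(G$subpop)
  stopifnot(length(pops) == 2L)
  g1 <- G$dosages[G$subpop == pops[1], , drop = FALSE]
  g2 <- G$dosages[G$subpop == pops[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(g1)); n2 <- 2 * colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / n1
  p2 <- colSums(g2, na.rm = TRUE) / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
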