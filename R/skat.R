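#' Staggered SNP windows
#'
#' Tiles each chromosome with fixed-width windows staggered by `step`
#' (default 3 kb windows every 1 kb, so consecutive windows overlap by
#' `width - step`). Windows holding no SNP are dropped.
#'
#' @param G a [genotype_matrix()] (or list with `chrom`, `pos`).
#' @param width,step window width and stagger in bp.
#' @return data frame `chrom, start, end, n_snps` with a list column
#'   `snps` of member SNP indices into `G`.
#' @export
make_windows <- function(G, width = 3000L, step = 1000L) {
  out <- list(); k <- 1L
  for (ch in unique(G$chrom)) {
    idx <- which(G$chrom == ch)
    pos <- G$pos[idx]
    if (length(pos) == 0L) next
    starts <- seq.int(1L, max(pos), by = step)
    for (s in starts) {
      e <- s + width - 1L
      mem <- idx[pos >= s & pos <= e]
      if (length(mem) == 0L) next
      out[[k]] <- list(chrom = ch, start = s, end = e, snps = mem)
      k <- k + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  df <- data.frame(chrom = vapply(out, `[[`, character(1), "chrom"),
                   start = vapply(out, `[[`, integer(1), "start"),
                   end = vapply(out, `[[`, integer(1), "end"),
                   n_snps = vapply(out, function(w) length(w$snps), integer(1)),
                   stringsAsFactors = FALSE)
  df$snps <- lapply(out, `[[`, "snps")
  df
}

#' Gaussian null model for SKAT
#'
#' Ordinary least squares of the (possibly untransformed) trait on the
#' covariates; SKAT only needs the residuals, the covariate projection
#' and the residual variance, so no normality-motivated transformation is
#' required — that burden is carried by the empirical p-values.
#'
#' @param y numeric trait (zeros allowed).
#' @param X covariate matrix including intercept (and structure
#'   covariates: genotype PCs for the P model, or ancestry fractions for
#'   the Q model).
#' @return object of class `skat_null` with residuals `r`, `qrX`,
#'   `sigma2`, `n`, `p`.
#' @export
skat_null <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient", call. = FALSE)
  r <- qr.resid(qrX, y)
  structure(list(r = r, qrX = qrX, sigma2 = sum(r^2) / (length(y) - ncol(X)),
                 n = length(y), p = ncol(X)),
            class = "skat_null")
}

#' MAF-based SKAT weights
#'
#' The classic beta-density weights `dbeta(maf, 1, 25)`, which upweight
#' rarer variants; `c(1, 1)` gives flat weights.
#'
#' @param maf minor allele frequencies.
#' @param beta_par two shape parameters of the beta density.
#' @return numeric weight vector.
#' @export
skat_weights <- function(maf, beta_par = c(1, 25)) {
  dbeta(maf, beta_par[1], beta_par[2])
}

#' SKAT kernel statistic for one window
#'
#' `Q = r' G W^2 G' r`, i.e. the squared norm of the weighted score
#' vector, with `r` the null-model residuals and `W = diag(w)`.
#'
#' @param r residual vector (from [skat_null()]).
#' @param G_w dosage matrix of the window's SNPs (samples x SNPs,
#'   missing mean-imputed beforehand).
#' @param weights per-SNP weights.
#' @return scalar `Q >= 0`.
#' @export
skat_stat <- function(r, G_w, weights) {
  G_w <- as.matrix(G_w)
  stopifnot(ncol(G_w) == length(weights))
  sum((drop(crossprod(G_w, r)) * weights)^2)
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Exact numerical inversion of the characteristic function (Imhof's
#' method, via `stats::integrate`), falling back to the Liu-Tang-Zhang
#' moment-matching approximation when the integration fails or returns a
#' value outside `[0, 1]`. The method actually used is attached as
#' attribute `"method"`.
#'
#' @param q observed statistic.
#' @param lambda positive weights (eigenvalues).
#' @return `P(sum lambda_i chi2_1 > q)`, clamped to `[1e-12, 1]`.
#' @export
pwchisq <- function(q, lambda) {
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L) return(structure(1, method = "degenerate"))
  # scale invariance: normalize so max eigenvalue is 1, and drop
  # components too small to move the distribution
  scl <- max(lambda)
  q <- q / scl
  lambda <- lambda[lambda / scl > 1e-6] / scl
  if (length(lambda) == 1L)
    return(structure(min(max(pchisq(q / lambda, df = 1, lower.tail = FALSE),
                             1e-12), 1), method = "exact"))
  imhof <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  # piecewise integration over doubling segments; the integrand amplitude
  # decays like u^-(1 + m/2) (m = #eigenvalues), so the analytic tail bound
  # below controls the truncation error once integration stops
  m <- length(lambda)
  tail_bound <- function(U)
    (2 / m) * U^(-m / 2) / (prod(sqrt(lambda)) * pi)
  p <- tryCatch({
    total <- 0; lo <- 0; hi <- 1
    for (seg in 1:60) {
      part <- tryCatch(
        integrate(imhof, lo, hi, rel.tol = 1e-10, abs.tol = 1e-13,
                  subdivisions = 2000L)$value,
        error = function(e) NA_real_)
      if (is.na(part)) {
        # oscillation outpaced the quadrature; accept the truncation if its
        # analytic bound is already negligible, otherwise fall back
        if (tail_bound(lo) < 1e-4) break else stop("integration failed")
      }
      total <- total + part
      if (tail_bound(hi) < 1e-8) break
      lo <- hi; hi <- 2 * hi
    }
    0.5 + total / pi
  }, error = function(e) NA_real_)
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6)
    return(structure(pwchisq_liu(q, lambda), method = "liu"))
  structure(min(max(p, 1e-12), 1), method = "imhof")
}

# Liu-Tang-Zhang noncentral chi-square moment matching
pwchisq_liu <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  p <- pchisq(tstar * sqrt(2) * a + l + d, df = l, ncp = d,
              lower.tail = FALSE)
  min(max(p, 1e-12), 1)
}

#' Parametric SKAT p-value for one window
#'
#' Under the Gaussian null the kernel statistic is distributed as a
#' positively weighted sum of chi-square(1) variables whose weights are
#' the nonzero eigenvalues of `sigma^2 W G'(I - H) G W`, with `H` the
#' covariate projection; the tail probability comes from [pwchisq()].
#'
#' @param Q observed statistic from [skat_stat()].
#' @param G_w window dosage matrix (mean-imputed).
#' @param weights per-SNP weights.
#' @param null a `skat_null`.
#' @return p-value with attributes `"method"` and `"lambda"`.
#' @export
skat_pvalue <- function(Q, G_w, weights, null) {
  A <- qr.resid(null$qrX, sweep(as.matrix(G_w), 2L, weights, "*"))
  lam <- eigen(crossprod(A) * null$sigma2, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10]
  p <- pwchisq(Q, lam)
  attr(p, "lambda") <- lam
  p
}

# Deterministic per-window RNG stream: identical results regardless of
# worker count or scheduling order.
window_seed <- function(seed, chrom, start) {
  h <- sum(utf8ToInt(as.character(chrom)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919 + start) %% 2147483629)
}

#' Adaptive Monte-Carlo empirical p-value for one window
#'
#' Freedman-Lane residual permutation: the covariate fit is held fixed,
#' the null-model residual vector is permuted and re-residualized on the
#' covariates (without this second projection the permutation null is
#' systematically too wide whenever the covariates — genotype PCs in
#' particular — absorb part of the window's dosage variance), the kernel
#' statistic is recomputed each time, and `p_emp = (b + 1) / (B + 1)` with
#' `b` the count of permuted statistics at least as large as the observed
#' one. `B` escalates through `stages` (capped at `B_max`), stopping early
#' once the normal-approximation confidence interval around `p_emp`
#' excludes `sig_level`; if the budget is exhausted with the interval
#' still straddling the threshold the result is flagged unconverged.
#'
#' @param r null-model residual vector.
#' @param G_w window dosage matrix (mean-imputed).
#' @param weights per-SNP weights.
#' @param Q_obs observed statistic.
#' @param sig_level significance threshold the interval is tested against.
#' @param B_max permutation budget.
#' @param stages escalation schedule.
#' @param seed integer seed for this window's RNG stream (see
#'   [window_seed()]).
#' @param conf_z z-multiplier of the stopping interval.
#' @param qrX QR decomposition of the null-model covariate matrix; when
#'   supplied, permuted residuals are projected off the covariates
#'   (recommended; [skat_scan()] always does this).
#' @return list `p_emp`, `B`, `converged`.
#' @export
skat_empirical <- function(r, G_w, weights, Q_obs, sig_level, B_max = 1e5,
                           stages = c(1e3, 1e4, 1e5), seed = 1L,
                           conf_z = 2.576, qrX = NULL) {
  GW <- sweep(as.matrix(G_w), 2L, weights, "*")
  # Q(perm) = || W G' (I - H) r_perm ||^2: fold the projection into GW
  if (!is.null(qrX)) GW <- qr.resid(qrX, GW)
  set.seed(seed)
  stages <- unique(pmin(stages[stages <= B_max * 1.0], B_max))
  if (length(stages) == 0L || max(stages) < B_max) stages <- c(stages, B_max)
  n <- length(r)
  b <- 0L; B <- 0L; converged <- FALSE
  for (target in stages) {
    while (B < target) {
      chunk <- min(500L, target - B)
      P <- vapply(seq_len(chunk), function(i) r[sample.int(n)],
                  numeric(n))
      Qs <- colSums(crossprod(GW, P)^2)
      b <- b + sum(Qs >= Q_obs)
      B <- B + chunk
    }
    p_hat <- (b + 1) / (B + 1)
    half <- conf_z * sqrt(p_hat * (1 - p_hat) / B)
    if (p_hat - half > sig_level || p_hat + half < sig_level) {
      converged <- TRUE
      break
    }
  }
  list(p_emp = (b + 1) / (B + 1), B = as.integer(B), converged = converged)
}

#' Windowed SKAT scan with gated empirical p-values
#'
#' Runs the parametric SKAT test over staggered windows and, for windows
#' whose parametric p-value falls at or below `p_gate`, computes an
#' adaptive Monte-Carlo empirical p-value. Each window draws from its own
#' RNG stream derived from `(seed, chrom, start)`, so results are
#' bit-identical across worker counts.
#'
#' @param y trait values (transformation optional).
#' @param X covariate matrix including intercept and structure covariates.
#' @param G a [genotype_matrix()].
#' @param width,step window geometry in bp.
#' @param beta_par SKAT weight shape (see [skat_weights()]).
#' @param maf_min drop SNPs below this MAF before windowing.
#' @param p_gate parametric gate below which empirical p-values are
#'   computed.
#' @param sig_level,B_max,stages forwarded to [skat_empirical()].
#' @param seed integer master seed.
#' @param workers `parallel::mclapply` worker count.
#' @return window results data frame: `chrom, start, end, n_snps, Q,
#'   p_param, p_method, p_emp, B, converged`.
#' @export
skat_scan <- function(y, X, G, width = 3000L, step = 1000L,
                      beta_par = c(1, 25), maf_min = 0.01,
                      p_gate = 1e-3, sig_level = 1e-5, B_max = 1e5,
                      stages = c(1e3, 1e4, 1e5), seed = 1L, workers = 1L) {
  keep <- which(!is.na(y))
  y <- y[keep]
  X <- as.matrix(X)[keep, , drop = FALSE]
  G <- subset_genotypes(G, samples = keep)
  maf <- snp_maf(G)
  G <- subset_genotypes(G, snps = which(!is.na(maf) & maf >= maf_min &
                                          !is_monomorphic(G)))
  null <- skat_null(y, X)
  win <- make_windows(G, width = width, step = step)
  if (nrow(win) == 0L) return(win)
  D <- G$dosages
  storage.mode(D) <- "double"
  mu <- colMeans(D, na.rm = TRUE)
  for (j in seq_len(ncol(D))) {
    z <- D[, j]; z[is.na(z)] <- mu[j]; D[, j] <- z
  }
  maf <- snp_maf(G)

  one <- function(i) {
    mem <- win$snps[[i]]
    Gw <- D[, mem, drop = FALSE]
    w <- skat_weights(maf[mem], beta_par)
    Q <- skat_stat(null$r, Gw, w)
    p_par <- skat_pvalue(Q, Gw, w, null)
    res <- c(Q = Q, p_param = as.numeric(p_par),
             p_emp = NA_real_, B = 0, converged = 1)
    meth <- attr(p_par, "method")
    if (as.numeric(p_par) <= p_gate) {
      emp <- skat_empirical(null$r, Gw, w, Q, sig_level = sig_level,
                            B_max = B_max, stages = stages,
                            seed = window_seed(seed, win$chrom[i], win$start[i]),
                            qrX = null$qrX)
      res["p_emp"] <- emp$p_emp
      res["B"] <- emp$B
      res["converged"] <- as.numeric(emp$converged)
    }
    list(res = res, method = meth)
  }
  rows <- if (workers > 1L)
    parallel::mclapply(seq_len(nrow(win)), one, mc.cores = workers)
  else lapply(seq_len(nrow(win)), one)
  M <- do.call(rbind, lapply(rows, `[[`, "res"))
  out <- win[, c("chrom", "start", "end", "n_snps")]
  out$Q <- M[, "Q"]
  out$p_param <- M[, "p_param"]
  out$p_method <- vapply(rows, `[[`, character(1), "method")
  out$p_emp <- M[, "p_emp"]
  out$B <- as.integer(M[, "B"])
  out$converged <- as.logical(M[, "converged"])
  out
}
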