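---
title: "Methods: association mapping for zero-inflated regeneration traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association mapping for zero-inflated regeneration traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenmap)
```

## The problem

Regeneration screens image the cut surfaces of stems weekly and segment
each image into background, unregenerated stem, callus and shoot pixels.
The two traits are the proportions of *plant* pixels (stem + callus +
shoot; background excluded) labelled callus and labelled shoot at each
week. Many genotypes never regenerate, so the traits carry a point mass
at zero next to a right-skewed continuous part. That mixture breaks the
residual-normality assumption of an ordinary linear-model GWAS, and no
single fix is free: excluding zeros discards the most recalcitrant
genotypes, dichotomizing discards the continuous signal, and power
transforms can overcorrect. `regenmap` therefore runs three
complementary association routes over the same genotypes and combines
their single-SNP evidence post hoc.

A note on the denominator: "total plant area" is taken to include
unregenerated stem, since the segmentation distinguishes three plant
classes and regenerated tissue is naturally expressed relative to the
whole explant. A mask with no plant pixels yields a missing trait, never
a zero, so empty images cannot inflate the zero class.

## Trait preparation

* **Replicate merging** (`merge_replicates`): mean of the two replicate
  plants; a single surviving replicate passes through; missing only when
  all replicates are missing.
* **Zero removal + Box–Cox** (`drop_zeros`, `boxcox_mle`) for the linear
  mixed model. The power parameter maximizes the profile log-likelihood
  $\ell(\lambda) = -\tfrac n2 \log\hat\sigma^2(\lambda) + (\lambda-1)\sum\log x_i$
  over $[-2, 2]$ (201-point grid polished by `optimize`).
* **Rank inverse-normal** (`rank_inverse_normal`) as the alternative for
  difficult distributions: Blom scores
  $z_i = \Phi^{-1}\{(r_i - 3/8)/(n + 1/4)\}$, mid-ranks for ties. The
  offset 3/8 is the standard Blom constant; nothing downstream is
  sensitive to the choice among the usual offsets.
* **Elbow thresholding** (`elbow_threshold`) for PC traits whose low end
  carries a spike of degenerate values: a Gaussian KDE (Silverman
  bandwidth, 512-point grid) is scanned for the maximum finite-difference
  second derivative strictly between its outermost local modes. A
  unimodal density, or a proposed cutoff below the 1st percentile, means
  "no elbow, no removal". The cutoff lands on the decaying flank of the
  spike — the point where the spike lets go of the axis — not in the
  middle of the empty valley, which is where a second-derivative rule
  genuinely puts it.
* **Outlier removal**: |z| > 4 on the transformed scale, configurable.
  Conservative on purpose: the skew *is* signal for these traits.
* **Trait PCA** (`trait_pca`): centered, unscaled (the inputs share the
  proportion scale), genotypes missing any batch trait excluded,
  genotypes that are zero across the whole batch removed *before* the
  decomposition (they form a degenerate spike in PC space); PC1/PC2
  scores become derived traits, later components are not analyzed.

Every transform is monotone on the values it keeps, so Spearman
correlation with the raw trait is exactly 1 — a property the tests
assert.

## Association models

**Linear mixed model** (`fit_lmm_null`, `lmm_gwas`). The null model
$y = Xb + u + e$, $u \sim N(0, \sigma^2_g K)$, $e \sim N(0, \sigma^2_e I)$
is fitted by REML using one eigendecomposition of the centered GRM
($K = ZZ'/m$, missing dosages mean-imputed) and a 1-D search over
$\log\delta$, $\delta = \sigma^2_e/\sigma^2_g$, on a 49-point grid
polished by `optimize` with explicit boundary checks. SNP heritability
is reported as the proportion of variance explained through $K$,
$h^2_{SNP} = \sigma^2_g\,\overline{\mathrm{tr}K}/(\sigma^2_g\,\overline{\mathrm{tr}K} + \sigma^2_e)$
with $\overline{\mathrm{tr}K} = \mathrm{tr}(K)/n$; this reduces to
$\sigma^2_g/(\sigma^2_g+\sigma^2_e)$ for a unit-diagonal kinship and,
unlike that simpler ratio, does not depend on the arbitrary scale of the
GRM. Per-SNP tests are Wald tests under the null variance components
(the standard population-parameters-previously-estimated shortcut);
with $K = I$ they collapse exactly to OLS t-tests. Traits with
$h^2_{SNP} \le 0.10$ are gated out of candidate interrogation by
default (overridable).

**Logistic mixed model** (`fit_glmm_null`, `glmm_gwas`,
`glmm_wald_refit`). The dichotomized trait (zero vs nonzero, tolerance
$10^{-12}$) is fitted by penalized quasi-likelihood: working response
from the current logistic fit, heteroscedastic LMM solve with the same
kinship, REML for the variance component each cycle, stopping when the
fixed effects move < 1e-6 or after 50 iterations (non-convergence marks
the fit unusable; fitted probabilities pinned at 0/1 raise a separation
error). Genome scans use the score test
$U = g'(y-\hat\mu)$, $\mathrm{Var}(U) = g'Pg$; Wald refits, which cost a
full PQL fit per SNP, are reserved for the members of windows that the
combination step flags (the two-round protocol below).

**Windowed SKAT** (`skat_scan`). On the untransformed trait — the
empirical p-values make no normality assumption, which is the point of
running this route — adjacent SNPs in 3 kb windows staggered by 1 kb are
tested jointly with $Q = r'GW^2G'r$, $W = \mathrm{diag}\,w_j$, default
$w_j = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25)$ density weights (flat
available), $r$ the residuals of the trait on covariates plus structure
covariates (genotype PCs, the "P model", by default; a fastSTRUCTURE-style
ancestry-fraction matrix, the "Q model", can be read from TSV instead).
The parametric p-value is the tail of a positively weighted sum of
$\chi^2_1$ variables (weights = nonzero eigenvalues of
$\sigma^2 WG'(I-H)GW$), computed by exact characteristic-function
inversion (Imhof's method: piecewise adaptive quadrature over doubling
segments with an analytic truncation bound; a single eigenvalue is
handled in closed form) with the Liu–Tang–Zhang moment-matching
approximation as fallback when the quadrature gives up; the method used
is recorded per window.

Windows whose parametric p falls at or below the gate (default 1e-3)
get an **adaptive Monte-Carlo empirical p-value**: Freedman–Lane
permutation of the null residuals with re-projection onto the covariate
complement — folding $(I-H)$ into $WG'$, without which the permutation
null is systematically too wide whenever the genotype-PC covariates
absorb part of the window's dosage variance — with
$p_{emp} = (b+1)/(B+1)$ and a staged budget
($10^3 \to 10^4 \to 10^5$ by default) that stops early when the
99%-style normal interval around $p_{emp}$ excludes the significance
level, flagging non-convergence otherwise. Each window draws from an RNG
stream derived from (seed, chromosome, window start), so results are
bit-identical for any worker count.

## ART combination

Single-SNP results are scanned for anchors: a SNP with $p < 10^{-5}$
within 500 bp of at least 5 further SNPs with $p < 10^{-4}$. Each anchor
emits a 1 kb window whose member p-values are combined by augmented rank
truncation with $k = \lceil L/2\rceil$ (the upper half of the ranked
members; ties in $p$ break by position). Conditional on the $(k{+}1)$-th
order statistic the $k$ smallest p-values are uniform order statistics
below it, so $\sum_{i\le k}\log(p_{(k+1)}/p_{(i)}) \sim \Gamma(k,1)$;
augmenting with $-\log F_{\mathrm{Beta}(k+1, L-k)}(p_{(k+1)})$, an
independent Exp(1), gives a $\Gamma(k{+}1,1)$ null and the combined
p-value is its upper tail. $L = 1$ reduces to the identity. A
Monte-Carlo calibration suite (uniformity of the combined p-value for
$L \in \{2, 6, 10\}$) guards the closed form against transcription
error. Member p-values are treated as exchangeable within the 1 kb
window — defensible here because LD in the emulated population decays
within a couple of kilobases.

For the logistic route ART runs twice: on score p-values first, then,
for windows passing the ART threshold, on Wald refits of the member
SNPs; windows with failed refits are flagged incomplete.

Three significance tiers, most to least conservative: the conservative
Bonferroni $\alpha/\#\mathrm{tests}$; Benjamini–Hochberg FDR at 0.10;
and the ART Bonferroni $\alpha/(\mathrm{genome\ bp}/1000)$, which for
the 394 Mb of contiguous assembled chromosomes gives
$\sim 1.27\times10^{-7}$. (Dividing 394 Mb by 1 kb gives
$3.94\times10^5$ windows; a window count three orders larger would be
inconsistent with that threshold.) Every conservative-Bonferroni call is
automatically an FDR call, which the tests assert as tier monotonicity.

## Peaks and genes

A tested locus (SNP position, or window midpoint for SKAT/ART) is a QTL
peak iff no other tested locus within 30 kb has a strictly smaller
p-value; equal-p ties resolve to the leftmost position. Peaks inside a
gene body take that gene (relation exonic or intragenic-nonexonic by
exon overlap, TSS distance 0); otherwise the nearest gene by bp gap wins
(equidistant flanks tie-break to the nearer strand-aware TSS, then
leftmost), the relation is 5′/3′ by which side of the gene the peak
sits, and two distances are reported: the strand-aware TSS distance (for
tables) and the boundary gap (for the ≤ 5 kb proximity flag) — the two
readings of "near the gene" that candidate reporting needs.

## What the synthetic data emulates — and what it does not

`sim_config()` defaults describe the study system: six ancestral
subpopulations (Balding–Nichols divergence, default $F_{st} = 0.1$),
ancestral MAFs uniform on [0.05, 0.5], two replicates, four weekly
timepoints with earlier weeks more zero-inflated (threshold offsets
+0.6, +0.25, 0, −0.15), a stem-diameter slope and four phenotyping-phase
offsets as covariates, and a liability-scale trait: planted causal SNPs
(standardized effects), a polygenic term whose covariance is the
realized GRM, and iid replicate noise summing to unit variance. The
observed trait is zero below the liability threshold (zero fraction
$\Phi(\tau)$ when covariates are off) and otherwise an affine squash of
the liability into a proportion range — callus up to 0.7 and shoot up to
0.3 of plant area, so the pair can never exceed the whole plant.
Phases are tied to subpopulation for a fraction of genotypes (default
0.5), deliberately confounding covariates with ancestry so that
structure correction is testable. An optional LD layer copies dosages
from the adjacent SNP with probability decaying in distance; it is off
by default because the emulated population is close to linkage
equilibrium beyond ~2 kb.

Passing tests on these simulations show that the statistics are
implemented correctly and calibrated under a structured, zero-inflated,
covariate-confounded null — they do not show that real segmentation
masks are accurate, that real LD is as simple as adjacent-SNP copying,
or that real effect architectures are as clean as a single planted
block.

## Numerical choices and problem sizes

Degenerate inputs fail loudly and early: constant traits (Box–Cox),
rank-deficient covariates (with the aliased columns named), non-PSD
kinship, monomorphic SNPs (skipped with a reason), all-zero traits,
plantless masks. Deterministic sign conventions (largest-magnitude
loading positive) make PCA reproducible; all coordinates are 1-based
closed intervals throughout.

The test suite runs its calibration at n = 300 samples × 2,000
SNPs/windows, parameter recovery at n = 600 × 5,000 SNPs over 20 seeds,
and the full-pipeline determinism check at n = 150 × 600 — sizes chosen
so the whole suite completes on a single CPU in minutes while leaving
each check statistically meaningful (binomial or KS bounds are computed,
not guessed). The heritability-recovery simulation is purely polygenic;
the causal-SNP recovery simulation plants its effect on a variant whose
realized MAF clears the scan's 0.05 filter, since a sub-threshold
variant is excluded before testing and would void the experiment rather
than measure power.

## Known limitations

* PQL is approximate; for very unbalanced dichotomies its variance
  component is biased downward (the score test remains calibrated, which
  is what the scans use).
* The adjacent-copy LD simulator produces only short-range, one-sided
  LD; it is a fixture for decay curves and window logic, not a
  coalescent.
* SKAT windows at desk scale hold few SNPs, where the parametric tail is
  already nearly exact; the empirical route matters most at biobank
  window sizes and extreme thresholds, which the staged budget is
  designed for but the test suite only samples.
* `assign_gene` reports the nearest gene; it does not model regulatory
  distance or chromatin contact, and the candidate it names is a
  hypothesis, not an identification.
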