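---
title: "Genetically independent phenotypes: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetically independent phenotypes: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipkit)
```

## The problem and the model

Complex traits that co-occur — such as chronic musculoskeletal pain reported
at the back, neck/shoulder, hip and knee — are often far more strongly
correlated at the genetic level (genetic correlations 0.56–0.87 in the
motivating UK-biobank analysis) than at the phenotypic level (0.18–0.28).
Single-trait GWAS then dilutes a largely shared genetic signal across several
noisy phenotypes.

`gipkit` addresses this by a modified principal component analysis. Let
$C_G$ be the $T \times T$ genetic covariance matrix of $T \ge 3$
*standardized* traits, estimated from GWAS summary statistics by LD Score
regression. Conventional PCA would rotate the traits by the eigenvectors of
the *phenotypic* covariance; here the rotation uses the eigenvectors of
$C_G$:

$$C_G = A \Lambda A^\top, \qquad \mathrm{GIP}_k = \sum_t A_{tk}\,\tilde y_t ,$$

with $\Lambda = \mathrm{diag}(\lambda_1 \ge \dots \ge \lambda_T)$. The
resulting components — *genetically independent phenotypes* (GIPs) — are
mutually uncorrelated at the genetic level; GIP1 captures the largest share
of genetic variance, $\lambda_1 / \sum_k \lambda_k$, and tends to load all
genetically correlated traits with near-equal weights, acting as the shared
("general") component. The trait-level attribution is
$A_{tk}^2 \lambda_k / (C_G)_{tt}$, whose rows sum to one exactly.

Because $C_G$ is estimated with noise, the loadings carry uncertainty. The
package propagates the joint block-jackknife sampling covariance $J$ of the
$T(T+1)/2$ unique entries of $C_G$ into Monte Carlo confidence intervals:
draw $\mathrm{vech}(C_G^*) \sim \mathcal N(\mathrm{vech}(\hat C_G), J)$,
eigendecompose each draw, match the draw's columns to the point estimate
greedily by maximal $|a_k^\top a_k^*|$ (guarding against eigenvalue-order
and sign switching under noise), and take 2.5%/97.5% percentiles per
loading. The default is 1000 draws.

### Determinism of the decomposition

Eigenvectors are defined only up to sign and, under ties, up to rotation.
The package fixes: columns ordered by descending eigenvalue; ties
($|\Delta\lambda| < 10^{-12}$) broken by lexicographic order of the absolute
loadings (so a scalar matrix yields identity loadings in trait order); signs
chosen so each column sums positive, falling back to a positive
largest-magnitude entry when the sum is ~0. Negative eigenvalues — possible
since $\hat C_G$ is an unconstrained estimate — are kept and flagged, never
truncated, so downstream uncertainty handling sees honest noise.

## Estimating the genetic covariance: simplified LD Score regression

For trait $t$ with association statistics $\chi^2_j = (\beta_j/s_j)^2$ at
SNP $j$ with LD score $\ell_j$ (sum of squared correlations with SNPs within
a window, plus 1 for the SNP itself),

$$E[\chi^2_j] = \frac{N h^2 \ell_j}{M} + a ,$$

where $M$ is the number of SNPs, $N$ the sample size and $a$ a free
intercept absorbing confounding. The cross-trait analogue regresses
$z_{1j} z_{2j}$ on $\ell_j$; its slope times $M/\sqrt{N_1 N_2}$ estimates
the genetic covariance and its intercept absorbs sample overlap.

Implementation choices, all tested against a noiseless oracle (constructed
$\chi^2$ exactly on the model line must be recovered to $10^{-10}$):

* **Weighting.** Two-pass weighted least squares: pass 1 with weights
  $1/(2\ell_j^2)$; pass 2 with $1/(2 (\hat a + N \hat\theta \ell_j/M)^2 \ell_j)$
  from the pass-1 fit (the expected-value term guarded below by 0.05). The
  same weight function serves the univariate and bivariate fits, so the
  bivariate fit of a table with itself reduces *exactly* to the univariate
  fit.
* **Standard errors.** Delete-one-block jackknife over 200 (default)
  contiguous SNP blocks, reusing the pass-2 weights. `build_cov_matrix()`
  runs all $T$ univariate and $T(T-1)/2$ bivariate fits on one common,
  allele-aligned SNP set with the *same* blocks, so the joint covariance
  $J$ of all entries comes from the same leave-one-block-out replicates.
  Empirically the jackknife SE is mildly conservative (factor ~1.2–1.6
  versus the replicate SD in our block-LD simulations), which we accept.
* **Outliers.** SNPs with $\chi^2 > \max(80,\ 0.001\,N)$ are excluded from
  the regression (single very large loci would otherwise dominate the fit
  and destabilize the intercept). The exclusion is applied jointly across
  traits inside `build_cov_matrix()` so the jackknife blocks stay aligned.
* **Allele harmonization.** Exact (EA, OA) match, or swap with sign flip;
  other combinations are dropped with a message. Fits with less than 50%
  SNP overlap error out.
* **Guardrails, not clamps.** Heritability estimates outside $[-0.5, 1.5]$
  are flagged; genetic correlations beyond $[\pm 1.05]$ are flagged;
  neither is truncated.

### Binary traits and the liability scale

Binary traits are analyzed by linear regression on the 0/1 scale (as
biobank-scale mixed-model software does), so LDSC estimates land on the
*observed* scale. Under the liability-threshold model with prevalence $K$
and threshold $z = \Phi^{-1}(1-K)$, the forward transform is

$$C_{G,\mathrm{obs}}(t,s) = C_{G,\mathrm{liab}}(t,s)\,
\frac{\varphi(z_t)\varphi(z_s)}{\sqrt{K_t(1-K_t)K_s(1-K_s)}},$$

(`expected_observed_scale_cov()`), and `liability_h2()` is the inverse
diagonal map $h^2_\mathrm{liab} = h^2_\mathrm{obs}
K^2(1-K)^2 / (P(1-P)\varphi(z)^2)$, which for a population cohort
($P = K$) reduces to the familiar $K(1-K)/\varphi(z)^2$ factor. Genetic
*correlations* are invariant under this rescaling, so the GIP loadings are
essentially scale-stable; heritabilities are not, which is why the package
reports the scale explicitly. No liability conversion is defined for a GIP
itself: a composite score has no prevalence, and we surface this as a
documented gap rather than invent one.

## GIP-level GWAS: two routes that must agree

With individual-level data, `gip_gwas_individual()` scores each person
($\tilde Y A$, traits standardized within the scored cohort) and runs the
same covariate-adjusted scan as the trait GWAS. With only summary
statistics, `gip_gwas_summary()` forms

$$\beta_{k}(j) = \sum_t A_{tk} \beta_t(j), \qquad
s_k(j)^2 = \sum_{t,s} A_{tk} A_{sk} (C_P)_{ts}\, s_t(j) s_s(j),$$

using the standard full-overlap approximation
$\mathrm{cov}(\hat\beta_t, \hat\beta_s) = (C_P)_{ts} s_t s_s$ and per-trait
effects on the standardized-phenotype scale. The two routes use the same
linear combination, so their effect sizes agree exactly and only the SE
approximation differs; on simulated cohorts the per-SNP z-scores correlate
beyond 0.999 with median $|\Delta z| < 10^{-3}$. Since the authoritative
derivation of the summary route is not public, we treat cross-route
agreement as the correctness contract.

Replication always applies the *frozen* discovery loadings
(`predict()`/`gip_scores()` on the new cohort); loadings are never refitted
downstream.

## Post-GWAS processing

* `gc_correct()` divides the association chi-square by the scan's LDSC
  intercept and recomputes the p-value in log space (no underflow through
  $10^{-300}$; a `LOG10P_GC` column carries the exact tail). Effect sizes
  stay; SEs are rescaled by $\sqrt{a}$. The pipeline applies
  $\max(1, \hat a)$: genomic control removes inflation and is never allowed
  to amplify statistics when the intercept estimate dips below 1 by noise.
* `ivw_meta()` is fixed-effects inverse-variance weighting with
  first-seen-cohort allele harmonization; SNPs present in a subset of
  cohorts are combined over that subset.
* `clump()` is purely positional: repeatedly take the most significant SNP
  below threshold, absorb everything within ±250 kb, deterministic
  (CHR, POS) tie-break. It is tested against an independently coded
  brute-force oracle.
* `replication_gate()` uses the Bonferroni threshold
  $\alpha / (\text{total discovery loci})$ *and* requires sign consistency.
  The sign requirement is a deliberate strengthening: a replication "hit"
  with an inverted effect direction is evidence against the locus, and in
  the reference tables the one sign-flipped locus also failed the p-value
  bound, so the rule changes no published verdict.
* `study_threshold()` is plain Bonferroni arithmetic (5e-8 / number of
  phenotypes for the study-wide bound).

## The synthetic cohort generator

The simulator exists so that every stage has a known truth; it emulates the
features the estimators rely on and nothing more.

* **LD.** Independent blocks with exchangeable within-block dosage
  correlation $\rho$, giving the closed-form LD score
  $\ell = 1 + (B-1)\rho^2$. Defaults cycle $\rho$ over 0.2/0.4/0.6/0.8
  across blocks: a *spread* of LD scores is what identifies the LDSC slope
  separately from its intercept, and a single genome-wide $\rho$ would make
  them nearly collinear. Blocks sit >500 kb apart (round-robin over 22
  chromosomes), so ±250 kb clumping can never merge blocks.
* **Genotypes.** Two haplotypes per individual; haplotype alleles are
  latent exchangeable-correlation Gaussians thresholded at each SNP's
  allele-frequency quantile, so dosages are exact 0/1/2 counts.
  Thresholding attenuates correlation below the latent value, so the latent
  correlation is *calibrated* per block by root-finding on the mean
  pairwise indicator correlation (bivariate normal rectangle probabilities
  via 64-node Gauss–Legendre quadrature). SNPs within a block share one
  MAF (±0.01 jitter) drawn from `maf_range`: SNPs in strong LD share
  genealogy and hence frequency, and near-equal margins keep high indicator
  correlations attainable at all.
* **Traits.** Infinitesimal model: per-SNP effect rows drawn from
  $\mathcal N(0, C_{G,\mathrm{liab}}/M)$ on the standardized-genotype
  scale; liability = genetic value + $\mathcal N(0, C_{E,\mathrm{liab}})$;
  binary traits threshold the liability at the $1-K$ quantile. A sparse
  large-effect component can be injected on top (`causal =`) for
  positive-control experiments. Two inert covariates (age-like, sex-like)
  exercise the adjustment plumbing without confounding recovery tests.
* **Default architecture.** `pain_architecture()` mirrors the printed
  ranges of the motivating study: liability $h^2 = 0.08$ per trait, uniform
  $r_g = 0.7$, prevalences 17.9/16.3/9.2/17.5%, and environmental
  correlation 0.40 calibrated through the exact thresholded-bivariate-normal
  correlation so the binary phenotypic correlations land mid-way in the
  printed 0.18–0.28 envelope.

What the simulator does *not* emulate: recombination-map LD decay,
imputation error, relatedness or population structure (the association
model is plain covariate-adjusted OLS — on unrelated simulated individuals
the mixed model's relatedness term has nothing to do), allele-frequency–
dependent architecture, or X-chromosome inheritance. Passing recovery tests
therefore demonstrates internal consistency of the estimators under the
stated model, not robustness to those real-data complications.

## Problem sizes and seeds used by the test-suite studies

The package's own validation studies (testthat suite and
`scripts/acceptance.R`) use sizes chosen to put the estimators in their
working regime while staying desk-scale:

* recovery study: 4 binary traits, liability $h^2 = 0.4$, $r_g = 0.7$,
  $K = 0.15$, $n = 6000$, $M = 2000$ (200 blocks × 10), 200 jackknife
  blocks — entrywise agreement with the liability-to-observed prediction
  within 2 jackknife SEs, GIP1 loadings within 0.15 of the exchangeable
  $(0.5, 0.5, 0.5, 0.5)$, pairwise GIP $|r_g|$ within 2 SEs of zero, and
  $h^2(\mathrm{GIP1})$ above every trait $h^2$. The heritability-
  concentration statement is a property of this exchangeable regime, not a
  theorem.
* coverage study: 50 replicates at $n = 4000$, $M = 500$, spectrum
  $(0.5, 0.25, 0.12, 0.05)$ on a fixed orthonormal basis (well-separated
  eigenvalues so the truth is identified), 400 Monte Carlo draws; empirical
  coverage of the 95% loading intervals must stay at or above 90%. At
  smaller $n$ the eigendecomposition's nonlinearity visibly erodes coverage
  toward that bound, which is why the study runs in the asymptotic regime.
* end-to-end controls: a shared causal variant (liability effect 0.25 per
  standardized allele on all four traits) must surface as a replicated GIP1
  locus in a 4000 + 3000 discovery/replication pipeline; a zero-heritability
  architecture must yield zero loci.

All stochastic steps take explicit seeds; pipelines derive per-stage seeds
from one master seed recorded in the run manifest, and identical
configurations reproduce outputs bit for bit.

## Known limitations

* OLS association scans only — no mixed models, logistic/saddlepoint tests,
  or relatedness handling; the simulator produces unrelated individuals by
  construction.
* No partitioned or constrained-intercept LDSC, no reference-panel LD
  scores; the published LDSC weighting constants are not reproduced
  bug-for-bug — the weighting here is fixed, documented and oracle-tested.
* Clumping is positional, not LD-based; no conditional/joint multi-signal
  analysis per locus.
* The summary-level GIP GWAS route assumes a fully overlapping cohort for
  all traits; partially overlapping designs would need a different
  covariance approximation.
* No liability-scale heritability is defined for a GIP (no prevalence
  exists for a composite); the observed-scale value is reported with its
  phenotypic variance normalization $\lambda_k / (a_k^\top C_P a_k)$.
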