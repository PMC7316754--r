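# Synthetic cohort simulator: LD-block genotypes and liability-threshold traits.
#
# Genotypes are built from two haplotypes per individual.  Within a block,
# haplotype alleles come from a latent exchangeable-correlation Gaussian
# thresholded at each SNP's allele-frequency quantile.  Thresholding shrinks
# the correlation of the resulting indicators below the latent correlation,
# so the latent value is calibrated (per block, by root finding on the mean
# pairwise indicator correlation) to make the realized inter-SNP dosage
# correlation match the requested value.

#' Specify an LD-block genotype layout
#'
#' Defines a genome of `n_blocks` independent LD blocks of `block_size` SNPs
#' each.  Within a block every SNP pair has (dosage) correlation
#' `within_block_r`; blocks are mutually independent and placed far enough
#' apart (>500 kb) that a +/-250 kb locus window never spans two blocks.
#'
#' @param n_blocks number of independent LD blocks.
#' @param block_size number of SNPs per block.
#' @param within_block_r target pairwise dosage correlation per block, each
#'   in `[0, 1)`; a scalar is recycled, a vector (recycled to `n_blocks`)
#'   gives blocks different LD strengths and hence a spread of LD scores --
#'   which is what identifies the LD score regression slope separately from
#'   its intercept.
#' @param maf_range lower and upper bound for per-SNP minor allele
#'   frequencies, both in `(0, 0.5]`.
#' @return an object of class `"block_spec"`.
#' @seealso [make_genotypes()], [true_ld_scores()]
#' @export
block_spec <- function(n_blocks, block_size,
                       within_block_r = c(0.2, 0.4, 0.6, 0.8),
                       maf_range = c(0.1, 0.5)) {
  if (length(n_blocks) != 1 || n_blocks < 1) stop_("n_blocks must be a positive count")
  if (length(block_size) != 1 || block_size < 1) stop_("block_size must be a positive count")
  if (any(within_block_r < 0) || any(within_block_r >= 1))
    stop_("within_block_r values must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_("maf_range must be an ordered pair inside (0, 0.5]")
  structure(list(n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 within_block_r = rep_len(within_block_r, n_blocks),
                 maf_range = maf_range),
            class = "block_spec")
}

#' Analytic LD scores of the simulated LD model
#'
#' For a block of `B` SNPs with uniform pairwise correlation `r`, every SNP's
#' LD score is `1 + (B - 1) * r^2` (the self term contributes 1).
#'
#' @param spec a [block_spec()].
#' @return numeric vector of length `n_blocks * block_size`.
#' @export
true_ld_scores <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  l <- 1 + (spec$block_size - 1) * spec$within_block_r^2
  rep(l, each = spec$block_size)
}

# latent correlation such that the mean pairwise indicator correlation over
# the block's threshold pairs equals the target dosage correlation
calibrate_latent_r <- function(target, thresholds) {
  if (target <= 0) return(0)
  B <- length(thresholds)
  if (B < 2) return(0)
  ij <- utils::combn(B, 2)
  t1 <- thresholds[ij[1, ]]
  t2 <- thresholds[ij[2, ]]
  f <- function(r) mean(phi_corr(r, t1, t2)) - target
  hi <- 0.9999
  if (f(hi) < 0) {
    warn_("target within-block correlation %.3f not attainable for drawn MAFs; using latent correlation %.4f", target, hi)
    return(hi)
  }
  uniroot(f, c(1e-9, hi), tol = 1e-6)$root
}

#' Simulate LD-block genotype dosages
#'
#' Draws per-SNP allele frequencies uniformly inside `spec$maf_range`, then
#' generates two haplotypes per individual from a thresholded latent Gaussian
#' with exchangeable within-block correlation (calibrated so that dosage
#' correlations match `spec$within_block_r`).  Dosage at a SNP is the sum of
#' the two haplotype alleles, hence always in `{0, 1, 2}`.
#'
#' Blocks are laid out round-robin over 22 autosomes; consecutive blocks on
#' the same chromosome start 1 Mb apart and a block spans less than 200 kb,
#' so distinct blocks are separated by more than 500 kb.
#'
#' @param n number of individuals (`n >= 2`).
#' @param spec a [block_spec()].
#' @param seed integer seed; all randomness is derived from it.
#' @return an object of class `"gip_cohort"`: a list with elements `dosages`
#'   (`n x M` matrix), `variant_meta` (data frame with `SNP`, `CHR`, `POS`,
#'   `A1`, `A2`, `MAF`, `BLOCK`), and `spec`.  `traits`, `covariates` and
#'   `truth` are filled by [simulate_traits()].
#' @export
make_genotypes <- function(n, spec, seed) {
  if (!inherits(spec, "block_spec")) stop_("spec must be a block_spec")
  if (length(n) != 1 || n < 2) stop_("n must be at least 2")
  if (missing(seed)) stop_("a seed is required")
  set.seed(as.integer(seed))

  B <- spec$block_size
  M <- spec$n_blocks * B
  dosages <- matrix(0L, n, M)
  maf_all <- numeric(M)
  step <- max(1L, as.integer(floor(2e5 / max(B, 1))))

  for (b in seq_len(spec$n_blocks)) {
    cols <- ((b - 1) * B + 1):(b * B)
    # one frequency per block with small per-SNP jitter: SNPs in strong LD
    # share genealogy, and near-equal margins keep high indicator
    # correlations attainable
    maf_b <- runif(1, spec$maf_range[1], spec$maf_range[2])
    maf <- pmin(pmax(maf_b + runif(B, -0.01, 0.01),
                     spec$maf_range[1]), spec$maf_range[2])
    thr <- qnorm(maf)
    r_lat <- calibrate_latent_r(spec$within_block_r[b], thr)
    dos <- matrix(0L, n, B)
    for (h in 1:2) {
      if (r_lat > 0) {
        u <- rnorm(n)
        Z <- sqrt(r_lat) * u + sqrt(1 - r_lat) * matrix(rnorm(n * B), n, B)
      } else {
        Z <- matrix(rnorm(n * B), n, B)
      }
      dos <- dos + (sweep(Z, 2, thr, "<=") * 1L)
    }
    dosages[, cols] <- dos
    maf_all[cols] <- maf
  }

  blk <- rep(seq_len(spec$n_blocks), each = B)
  chr <- ((blk - 1) %% 22) + 1
  tier <- (blk - 1) %/% 22
  pos <- tier * 1e6 + 1 + (rep(seq_len(B), spec$n_blocks) - 1) * step
  meta <- data.frame(
    SNP = sprintf("snp_%d_%d", blk, rep(seq_len(B), spec$n_blocks)),
    CHR = as.integer(chr),
    POS = as.integer(pos),
    A1 = "A", A2 = "G",
    MAF = maf_all,
    BLOCK = blk,
    stringsAsFactors = FALSE
  )
  colnames(dosages) <- meta$SNP

  structure(list(dosages = dosages, variant_meta = meta, traits = NULL,
                 covariates = NULL, truth = NULL, spec = spec),
            class = "gip_cohort")
}

#' @export
print.gip_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNPs (%d blocks of %d)\n",
              nrow(x$dosages), ncol(x$dosages), x$spec$n_blocks, x$spec$block_size))
  if (!is.null(x$traits))
    cat(sprintf("Traits: %s\n", paste(colnames(x$traits), collapse = ", ")))
  invisible(x)
}

#' Define a multi-trait liability architecture
#'
#' Describes `T >= 3` traits on the liability scale: each trait has a latent
#' standardized Gaussian liability decomposed into a genetic and an
#' environmental part, `C_G + C_E` having unit diagonal.  Binary traits arise
#' by thresholding the liability at the `1 - K` quantile (`K` = prevalence).
#'
#' Either supply `C_G` and `C_E` directly, or the shorthand `h2` (liability
#' heritabilities), `rg` (genetic correlation, scalar or matrix) and
#' `env_cor` (environmental correlation, scalar or matrix).
#'
#' @param h2 length-`T` vector of liability-scale heritabilities.
#' @param rg genetic correlation between traits; scalar (exchangeable) or
#'   `T x T` correlation matrix.
#' @param prevalence length-`T` vector of trait prevalences in `(0, 1)`.
#' @param env_cor environmental correlation; scalar or `T x T` matrix.
#' @param C_G,C_E explicit liability-scale genetic and environmental
#'   covariance matrices (override `h2`/`rg`/`env_cor`).
#' @param binary if `TRUE`, traits are thresholded to 0/1; otherwise the
#'   continuous liabilities are returned.
#' @param traits trait names.
#' @return an object of class `"trait_architecture"`.
#' @export
trait_architecture <- function(h2 = NULL, rg = 0, prevalence, env_cor = 0,
                               C_G = NULL, C_E = NULL, binary = TRUE,
                               traits = NULL) {
  if (is.null(C_G)) {
    if (is.null(h2)) stop_("supply either C_G or h2")
    T_ <- length(h2)
    Rg <- if (is.matrix(rg)) rg else {m <- matrix(rg, T_, T_); diag(m) <- 1; m}
    C_G <- diag(sqrt(h2), T_) %*% Rg %*% diag(sqrt(h2), T_)
  }
  T_ <- nrow(C_G)
  if (is.null(C_E)) {
    e2 <- 1 - diag(C_G)
    Re_ <- if (is.matrix(env_cor)) env_cor else {m <- matrix(env_cor, T_, T_); diag(m) <- 1; m}
    C_E <- diag(sqrt(e2), T_) %*% Re_ %*% diag(sqrt(e2), T_)
  }
  if (!isTRUE(all.equal(dim(C_G), dim(C_E))))
    stop_("C_G and C_E must be conformable")
  if (max(abs(diag(C_G) + diag(C_E) - 1)) > 1e-8)
    stop_("C_G + C_E must have unit diagonal (standardized liabilities)")
  if (!is_psd(C_G)) stop_("C_G is not positive semidefinite")
  if (!is_psd(C_E)) stop_("C_E is not positive semidefinite")
  if (length(prevalence) == 1) prevalence <- rep(prevalence, T_)
  if (length(prevalence) != T_ || any(prevalence <= 0) || any(prevalence >= 1))
    stop_("prevalence must be a length-%d vector inside (0, 1)", T_)
  traits <- traits %||% paste0("trait", seq_len(T_))
  dimnames(C_G) <- dimnames(C_E) <- list(traits, traits)
  structure(list(n_traits = T_, C_G_liab = C_G, C_E_liab = C_E,
                 prevalence = setNames(prevalence, traits),
                 binary = binary, traits = traits),
            class = "trait_architecture")
}

#' Four-trait chronic-pain-like architecture
#'
#' A ready-made [trait_architecture()] emulating four chronic musculoskeletal
#' pain traits (back, neck/shoulder, hip, knee) as reported for a large
#' population cohort: liability-scale heritability 8% per trait (observed
#' scale 2-4% given the prevalences), uniform genetic correlation 0.7
#' (printed range 0.56-0.87), prevalences 17.9%, 16.3%, 9.2% and 17.5%, and
#' an environmental liability correlation of 0.40 calibrated (via the exact
#' thresholded-bivariate-normal correlation) so that the pairwise phenotypic
#' correlations of the binary traits fall in the printed 0.18-0.28 envelope.
#'
#' @return a `"trait_architecture"` object.
#' @export
pain_architecture <- function() {
  trait_architecture(
    h2 = rep(0.08, 4), rg = 0.7,
    prevalence = c(0.179, 0.163, 0.092, 0.175),
    env_cor = 0.40, binary = TRUE,
    traits = c("back", "neck_shoulder", "hip", "knee")
  )
}

#' Simulate traits on a genotyped cohort
#'
#' Draws per-SNP effects for every SNP (infinitesimal model) from a zero-mean
#' multivariate normal with covariance `C_G_liab / M` on the standardized
#' genotype scale, forms genetic values `g = X_std %*% beta`, adds
#' environmental deviations `e ~ MVN(0, C_E_liab)`, and thresholds the
#' liability `L = g + e` at the `1 - K` quantile when the architecture is
#' binary.  Optionally injects fixed large effects at named SNPs (a sparse
#' component on top of the polygenic background) for positive-control
#' experiments.
#'
#' Also simulates two inert covariates (an age-like and a sex-like column)
#' with zero true effect, to exercise covariate adjustment downstream.
#'
#' @param cohort a `"gip_cohort"` from [make_genotypes()].
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @param causal optional list with elements `snp` (SNP ids) and `beta`
#'   (matrix `length(snp) x T`, or a vector for one SNP) of liability-scale
#'   effects per standardized allele.
#' @return the cohort with `traits` (`n x T`, 0/1 or continuous),
#'   `covariates` (`age`, `sex`) and `truth` (architecture, per-SNP effect
#'   matrix, genetic values, true LD scores) filled in.
#' @export
simulate_traits <- function(cohort, arch, seed, causal = NULL) {
  stopifnot(inherits(cohort, "gip_cohort"), inherits(arch, "trait_architecture"))
  if (missing(seed)) stop_("a seed is required")
  set.seed(as.integer(seed))

  X <- cohort$dosages
  n <- nrow(X); M <- ncol(X); T_ <- arch$n_traits
  sds <- apply(X, 2, sd)
  ok <- sds > 0
  Xs <- matrix(0, n, M, dimnames = dimnames(X))
  Xs[, ok] <- scale(X[, ok, drop = FALSE])

  beta <- matrix(rnorm(M * T_), M, T_) %*% psd_sqrt(arch$C_G_liab / M)
  rownames(beta) <- colnames(X); colnames(beta) <- arch$traits
  if (!is.null(causal)) {
    cb <- causal$beta
    if (is.null(dim(cb))) cb <- matrix(cb, nrow = 1)
    idx <- match(causal$snp, colnames(X))
    if (anyNA(idx)) stop_("causal SNP id not found in cohort")
    beta[idx, ] <- beta[idx, ] + cb
  }
  g <- Xs %*% beta
  e <- matrix(rnorm(n * T_), n, T_) %*% psd_sqrt(arch$C_E_liab)
  L <- g + e
  colnames(L) <- arch$traits

  if (arch$binary) {
    thr <- qnorm(1 - arch$prevalence)
    y <- sweep(L, 2, thr, ">") * 1
  } else {
    y <- L
  }
  colnames(y) <- arch$traits

  cohort$traits <- y
  cohort$covariates <- cbind(age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.54))
  cohort$truth <- list(arch = arch, beta = beta, genetic_values = g,
                       liability = L, ld_scores = true_ld_scores(cohort$spec),
                       causal = causal)
  cohort
}

#' Expected observed-scale genetic covariance of binary traits
#'
#' Forward transform from the liability to the observed (standardized 0/1)
#' scale: entry `(t, s)` is
#' `C_G_liab[t, s] * phi(z_t) * phi(z_s) / sqrt(K_t (1 - K_t) K_s (1 - K_s))`
#' with `z_t = qnorm(1 - K_t)`.  The diagonal is the standard
#' liability-to-observed heritability transform; this is what LD Score
#' regression on the binary traits is expected to recover.
#'
#' @param arch a binary [trait_architecture()].
#' @return `T x T` matrix on the observed scale.
#' @seealso [liability_h2()] for the inverse (diagonal) transform.
#' @export
expected_observed_scale_cov <- function(arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (!arch$binary) stop_("architecture is not binary; observed scale equals liability scale")
  K <- arch$prevalence
  z <- qnorm(1 - K)
  f <- dnorm(z) / sqrt(K * (1 - K))
  arch$C_G_liab * (f %o% f)
}
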