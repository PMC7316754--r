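# shared fixtures; heavyweight simulations are cached so several test files
# can reuse them within one run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# minimal sumstats table for constructed fixtures
toy_sumstats <- function(beta, se, snp = paste0("s", seq_along(beta)),
                         chr = 1L, pos = seq_along(beta), ea = "A", oa = "G",
                         eaf = 0.3, n = 1000) {
  data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa, EAF = eaf,
             BETA = beta, SE = se, P = 2 * pnorm(-abs(beta / se)), N = n,
             stringsAsFactors = FALSE)
}

# noiseless univariate LDSC fixture: chi2 exactly on the model line
noiseless_chi2_fixture <- function(N = 1000, M = 100, h2 = 0.5,
                                   ld = rep(1:10, each = 10)) {
  chi2 <- 1 + N * h2 * ld / M
  ss <- toy_sumstats(beta = sqrt(chi2), se = 1, n = N)
  list(ss = ss, ld = ld, N = N, M = M, h2 = h2)
}

# random PSD covariance matrix with unit-bounded diagonal
random_psd <- function(T_, scale = 0.05) {
  W <- matrix(rnorm(T_ * T_), T_)
  S <- crossprod(W) / T_
  S * scale
}

# continuous-trait study: genotypes, traits, standardized per-trait scans
sim_continuous_study <- function(n, spec, arch, seed) {
  co <- make_genotypes(n, spec, seed = seed)
  co <- simulate_traits(co, arch, seed = seed + 1L)
  ss <- lapply(colnames(co$traits), function(tr)
    gwas_scan(co, tr, standardize_trait = TRUE))
  names(ss) <- colnames(co$traits)
  list(cohort = co, ss = ss,
       ld_true = setNames(true_ld_scores(spec), co$variant_meta$SNP))
}

# the main recovery study: 4 binary traits, liability h2 = 0.4, r_g = 0.7,
# prevalence 0.15, n = 6000, M = 2000 LD-block SNPs
recovery_sim <- function() cached("recovery", function() {
  spec <- block_spec(200, 10)
  arch <- trait_architecture(h2 = rep(0.4, 4), rg = 0.7,
                             prevalence = 0.15, env_cor = 0)
  co <- make_genotypes(6000, spec, seed = 421)
  co <- simulate_traits(co, arch, seed = 422)
  ld <- ld_scores_empirical(co)
  ss <- lapply(colnames(co$traits), function(tr)
    gwas_scan(co, tr, covariates = co$covariates, standardize_trait = TRUE))
  names(ss) <- colnames(co$traits)
  est <- build_cov_matrix(ss, ld, M = 2000, n_blocks = 200)
  model <- suppressWarnings(gip(est, mc_draws = 0))
  gips_ind <- gip_gwas_individual(co, model, covariates = co$covariates)
  C_P <- cor(co$traits)
  gips_sum <- gip_gwas_summary(ss, model, C_P)
  gip_est <- build_cov_matrix(gips_ind, ld, M = 2000, n_blocks = 200)
  list(spec = spec, arch = arch, cohort = co, ld = ld, trait_ss = ss,
       est = est, model = model, gips_ind = gips_ind, gips_sum = gips_sum,
       C_P = C_P, gip_est = gip_est)
})

# greedy |inner product| matching of estimated loading columns to a
# reference basis, with sign orientation; returns the reoriented reference
match_loadings <- function(A_hat, A_ref) {
  T_ <- ncol(A_hat)
  S <- abs(crossprod(A_hat, A_ref))
  perm <- integer(T_); used <- logical(T_)
  for (s in seq_len(T_)) {
    S[, used] <- -Inf
    ij <- arrayInd(which.max(S), dim(S))
    perm[ij[1]] <- ij[2]; used[ij[2]] <- TRUE
    S[ij[1], ] <- -Inf
  }
  A <- A_ref[, perm, drop = FALSE]
  flip <- colSums(A_hat * A) < 0
  A[, flip] <- -A[, flip]
  A
}
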