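test_that("eigendecomposition conventions are deterministic", {
  # degenerate spectrum: identity loadings in trait order
  f <- gip(diag(3) * 0.03)
  expect_equal(unname(f$loadings), diag(3))
  expect_equal(unname(f$eigenvalues), rep(0.03, 3))

  # 2 x 2 by hand (override for the toy size)
  f2 <- gip(matrix(c(0.04, 0.03, 0.03, 0.04), 2), allow_pairs = TRUE)
  expect_equal(unname(f2$eigenvalues), c(0.07, 0.01), tolerance = 1e-12)
  expect_equal(unname(f2$loadings[, 1]), c(0.70711, 0.70711), tolerance = 1e-5)
  expect_equal(unname(f2$loadings[, 2]), c(0.70711, -0.70711), tolerance = 1e-5)
  expect_error(gip(matrix(c(0.04, 0.03, 0.03, 0.04), 2)), "three or more")

  # exchangeable 4-trait case: equal loadings, lambda1 = h2 (1 + 3 rg)
  C <- matrix(0.03 * 0.7, 4, 4); diag(C) <- 0.03
  f4 <- gip(C)
  expect_equal(unname(f4$loadings[, 1]), rep(0.5, 4), tolerance = 1e-10)
  expect_equal(unname(f4$eigenvalues[1]), 0.093, tolerance = 1e-12)
  expect_equal(unname(f4$explained_total[1]), 0.775, tolerance = 1e-12)

  # sign convention: every column sums >= 0 (or has its largest entry positive)
  set.seed(91)
  for (i in 1:20) {
    fr <- suppressWarnings(gip(random_psd(4)))
    s <- colSums(fr$loadings)
    big <- vapply(seq_len(4), function(k)
      fr$loadings[which.max(abs(fr$loadings[, k])), k], numeric(1))
    expect_true(all(s > -1e-12 | big > 0))
  }

  expect_error(gip(matrix(c(1, 0.5, 0.2, 1), 2), allow_pairs = TRUE),
               "asymmetric")
})

test_that("eigen identities hold on random PSD matrices", {
  set.seed(92)
  for (i in 1:30) {
    T_ <- sample(3:6, 1)
    C <- random_psd(T_)
    f <- gip(C)
    A <- f$loadings
    expect_lt(max(abs(crossprod(A) - diag(T_))), 1e-10)
    expect_lt(max(abs(A %*% diag(f$eigenvalues) %*% t(A) - C)), 1e-10)
    expect_equal(sum(f$explained_total), 1, tolerance = 1e-10)
    expect_equal(unname(rowSums(f$explained_per_trait)), rep(1, T_),
                 tolerance = 1e-10)
  }
  expect_error(explained_variance(suppressWarnings(gip(-diag(3) * 0.1))),
               "not positive")
})

test_that("Monte Carlo CIs degenerate correctly and scale with J", {
  C <- diag(c(0.06, 0.04, 0.02)) + 0.005
  f <- gip(C)
  p <- 6
  ci0 <- monte_carlo_loading_ci(f, J = matrix(0, p, p), n_draws = 200, seed = 1)
  expect_equal(max(ci0$upper - ci0$lower), 0)

  J1 <- diag(p) * 1e-5
  ci1 <- monte_carlo_loading_ci(f, J = J1, n_draws = 3000, seed = 2)
  ci2 <- monte_carlo_loading_ci(f, J = J1 / 4, n_draws = 3000, seed = 3)
  ratio <- mean(ci2$upper - ci2$lower) / mean(ci1$upper - ci1$lower)
  expect_gt(ratio, 0.45); expect_lt(ratio, 0.55)

  expect_error(monte_carlo_loading_ci(f, J = J1, n_draws = 50), "at least 100")
  expect_error(monte_carlo_loading_ci(f, J = diag(3)), "must be")
})

test_that("GIP scores apply frozen loadings to standardized traits", {
  set.seed(95)
  Y <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, paste0("trait", 1:3)))
  fI <- gip(diag(3) * 0.03)
  sc <- gip_scores(Y, fI)
  expect_equal(unname(sc), unname(apply(Y, 2, standardize)), tolerance = 1e-12)

  # sample covariance of scores equals t(A) C_P_hat A exactly
  C <- random_psd(3, 0.08)
  f <- suppressWarnings(gip(C + diag(3) * 0.02))
  sc2 <- gip_scores(Y, f)
  Cp_hat <- cor(Y)
  expect_equal(cov(sc2), t(f$loadings) %*% Cp_hat %*% f$loadings,
               tolerance = 1e-10, ignore_attr = TRUE)

  colnames(Y) <- c("a", "b", "c")
  expect_error(gip_scores(Y, f), "trait names")
})

test_that("predicted GIP phenotypic correlations follow the quadratic forms", {
  C <- matrix(0.03 * 0.7, 4, 4); diag(C) <- 0.03
  f <- gip(C)
  # orthonormal loadings + identity C_P: GIPs phenotypically uncorrelated
  pc_I <- predict_gip_pheno_corr(f, diag(4))
  expect_equal(unname(pc_I$gip_corr), diag(4), tolerance = 1e-10)

  # exchangeable C_P with exchangeable loadings: GIP1 orthogonal to GIP2
  Cp <- matrix(0.23, 4, 4); diag(Cp) <- 1
  pc <- predict_gip_pheno_corr(f, Cp)
  expect_equal(pc$gip_corr[1, 2], 0, tolerance = 1e-10)

  # matches the empirical correlation of actual GIP scores
  set.seed(96)
  Y <- matrix(rnorm(2000), 500, 4,
              dimnames = list(NULL, paste0("trait", 1:4)))
  sc <- gip_scores(Y, f)
  pc_emp <- predict_gip_pheno_corr(f, cor(Y))
  expect_equal(cor(sc), unname(pc_emp$gip_corr), tolerance = 1e-10,
               ignore_attr = TRUE)

  # h2 of the components: lambda / (a' C_P a); closed form on exchangeable
  h2g <- gip_h2(f, Cp)
  expect_equal(unname(h2g[1]), 0.093 / 1.69, tolerance = 1e-10)
  fI <- gip(diag(3) * 0.03)
  expect_equal(unname(gip_h2(fI, diag(3))), rep(0.03, 3), tolerance = 1e-12)
})

test_that("summary-route GIP GWAS has the closed-form SE and identity limit", {
  # identity loadings + identity C_P: output equals input
  fI <- gip(diag(3) * 0.03)
  ss <- toy_sumstats(beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.03, 0.04))
  lst <- list(trait1 = ss, trait2 = ss, trait3 = ss)
  out <- gip_gwas_summary(lst, fI, diag(3))
  expect_equal(out$GIP1$BETA, ss$BETA, tolerance = 1e-12)
  expect_equal(out$GIP1$SE, ss$SE, tolerance = 1e-12)

  # two traits, equal SEs s, loading (0.70711, 0.70711): SE = s sqrt(1 + rho)
  f2 <- gip(matrix(c(0.04, 0.03, 0.03, 0.04), 2), allow_pairs = TRUE)
  s <- 0.01; rho <- 0.3
  Cp <- matrix(c(1, rho, rho, 1), 2)
  pair <- list(trait1 = toy_sumstats(beta = 0.1, se = s),
               trait2 = toy_sumstats(beta = 0.2, se = s))
  out2 <- gip_gwas_summary(pair, f2, Cp)
  expect_equal(out2$GIP1$SE, s * sqrt(1 + rho), tolerance = 1e-5)
})

test_that("individual and summary routes agree on a simulated cohort", {
  arch <- trait_architecture(h2 = c(0.4, 0.3, 0.25), rg = 0.6,
                             prevalence = 0.5, env_cor = 0.2, binary = FALSE)
  sim <- sim_continuous_study(2000, block_spec(20, 10), arch, seed = 101)
  est <- build_cov_matrix(sim$ss, sim$ld_true, M = 200, n_blocks = 40)
  model <- suppressWarnings(gip(est, mc_draws = 0))
  ind <- gip_gwas_individual(sim$cohort, model)
  smry <- gip_gwas_summary(sim$ss, model, cor(sim$cohort$traits))
  for (k in names(ind)) {
    zi <- ind[[k]]$BETA / ind[[k]]$SE
    zs <- smry[[k]]$BETA / smry[[k]]$SE
    expect_gt(cor(zi, zs), 0.999)
    expect_lt(median(abs(zi - zs)), 0.05)
  }
})

test_that("a shared causal variant gains power on GIP1 and null GIPs stay calibrated", {
  # shared causal SNP: GIP1 chi-square beats every single-trait chi-square
  arch <- trait_architecture(h2 = rep(0.2, 4), rg = 0.6, prevalence = 0.5,
                             env_cor = 0.2, binary = FALSE)
  co <- make_genotypes(3000, block_spec(20, 10), seed = 111)
  co <- simulate_traits(co, arch, seed = 112,
                        causal = list(snp = "snp_5_3", beta = rep(0.15, 4)))
  ld <- setNames(true_ld_scores(co$spec), co$variant_meta$SNP)
  ss <- lapply(colnames(co$traits), function(tr)
    gwas_scan(co, tr, standardize_trait = TRUE))
  names(ss) <- colnames(co$traits)
  est <- build_cov_matrix(ss, ld, M = 200, n_blocks = 40)
  model <- suppressWarnings(gip(est, mc_draws = 0))
  gips <- gip_gwas_individual(co, model)
  j <- which(gips$GIP1$SNP == "snp_5_3")
  chi_gip1 <- (gips$GIP1$BETA[j] / gips$GIP1$SE[j])^2
  chi_traits <- vapply(ss, function(s) (s$BETA[j] / s$SE[j])^2, numeric(1))
  expect_gt(chi_gip1, max(chi_traits))

  # null architecture: a GIP1 scan is calibrated when the loadings come from
  # an independent cohort (within-cohort eigenvector selection would
  # overfit the noise maximum, so the scan is scored on a second cohort)
  arch0 <- trait_architecture(h2 = rep(0, 3), rg = 0, prevalence = 0.5,
                              env_cor = 0.3, binary = FALSE)
  fitco <- make_genotypes(2000, block_spec(30, 10), seed = 113)
  fitco <- simulate_traits(fitco, arch0, seed = 114)
  ld0 <- setNames(true_ld_scores(fitco$spec), fitco$variant_meta$SNP)
  ss0 <- lapply(colnames(fitco$traits), function(tr)
    gwas_scan(fitco, tr, standardize_trait = TRUE))
  names(ss0) <- colnames(fitco$traits)
  est0 <- build_cov_matrix(ss0, ld0, M = 300, n_blocks = 30)
  model0 <- suppressWarnings(gip(est0, mc_draws = 0))
  # scored cohort: many independent null SNPs so the median-based lambda_GC
  # has sampling SD ~0.02
  co0 <- make_genotypes(300, block_spec(10, 1000, within_block_r = 0),
                        seed = 115)
  co0 <- simulate_traits(co0, arch0, seed = 116)
  g0 <- gip_gwas_individual(co0, model0)
  lambda_gc <- median((g0$GIP1$BETA / g0$GIP1$SE)^2) / qchisq(0.5, 1)
  expect_gt(lambda_gc, 0.95); expect_lt(lambda_gc, 1.05)
})
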