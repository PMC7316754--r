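test_that("block_spec and trait_architecture validate their inputs", {
  expect_error(block_spec(0, 10), "n_blocks")
  expect_error(block_spec(5, 10, within_block_r = 1), "within_block_r")
  expect_error(block_spec(5, 10, maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(block_spec(5, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(make_genotypes(1, block_spec(2, 3), seed = 1), "at least 2")
  expect_error(make_genotypes(10, block_spec(2, 3)), "seed")
  expect_error(trait_architecture(h2 = c(0.5, 0.5), rg = 0, prevalence = 1.2),
               "prevalence")
  # C_G + C_E must have unit diagonal
  expect_error(trait_architecture(C_G = diag(2) * 0.5, C_E = diag(2) * 0.2,
                                  prevalence = 0.1), "unit diagonal")
  expect_error(trait_architecture(C_G = matrix(c(1, 2, 2, 1) * 0.1, 2),
                                  C_E = diag(c(0.9, 0.9)), prevalence = 0.1),
               "positive semidefinite")
})

test_that("genotype generation is deterministic, bounded and respects MAF", {
  spec <- block_spec(3, 5, within_block_r = 0.4)
  co1 <- make_genotypes(500, spec, seed = 7)
  co2 <- make_genotypes(500, spec, seed = 7)
  expect_identical(co1$dosages, co2$dosages)
  expect_identical(co1$variant_meta, co2$variant_meta)
  expect_true(all(co1$dosages %in% 0:2))

  # realized allele frequency within 4 binomial SDs of the drawn MAF
  maf_hat <- colMeans(co1$dosages) / 2
  tol <- 4 * sqrt(co1$variant_meta$MAF * (1 - co1$variant_meta$MAF) / (2 * 500))
  expect_true(all(abs(maf_hat - co1$variant_meta$MAF) < tol))

  # block layout: whole block spans < 250 kb; blocks on the same chromosome
  # separated by > 500 kb
  meta <- co1$variant_meta
  span <- tapply(meta$POS, meta$BLOCK, function(p) diff(range(p)))
  expect_true(all(span < 250000))
  for (chr in unique(meta$CHR)) {
    sub <- meta[meta$CHR == chr, ]
    for (b1 in unique(sub$BLOCK)) for (b2 in unique(sub$BLOCK)) {
      if (b1 < b2) {
        gap <- min(sub$POS[sub$BLOCK == b2]) - max(sub$POS[sub$BLOCK == b1])
        expect_gt(abs(gap), 500000)
      }
    }
  }
})

test_that("within-block dosage correlation matches the requested value", {
  # independence case: mean pairwise correlation centered on zero
  n <- 2000
  co0 <- make_genotypes(n, block_spec(3, 6, within_block_r = 0), seed = 11)
  r0 <- sapply(1:3, function(b) {
    C <- cor(co0$dosages[, ((b - 1) * 6 + 1):(b * 6)])
    mean(C[upper.tri(C)])
  })
  expect_lt(abs(mean(r0)), 3 / sqrt(n))

  # calibrated case: B = 10, rho = 0.5, n = 5000
  co5 <- make_genotypes(5000, block_spec(5, 10, within_block_r = 0.5), seed = 12)
  r5 <- sapply(1:5, function(b) {
    C <- cor(co5$dosages[, ((b - 1) * 10 + 1):(b * 10)])
    mean(C[upper.tri(C)])
  })
  expect_gt(mean(r5), 0.45)
  expect_lt(mean(r5), 0.55)
})

test_that("analytic LD scores follow the closed form", {
  expect_equal(unique(true_ld_scores(block_spec(4, 1, 0.9))), 1)
  expect_equal(unique(true_ld_scores(block_spec(2, 10, 0.5))), 3.25)
  # B = 2, rho -> 1 gives l -> 2
  expect_equal(unique(true_ld_scores(block_spec(1, 2, 1 - 1e-6))), 2,
               tolerance = 1e-5)
  # per-block correlations give per-block scores
  l <- true_ld_scores(block_spec(2, 10, c(0, 0.5)))
  expect_equal(unique(l), c(1, 3.25))
})

test_that("liability simulation honours the architecture", {
  spec <- block_spec(5, 10)
  # zero genetic covariance: genetic values identically zero and trait
  # correlations driven by the environment alone
  arch0 <- trait_architecture(h2 = rep(0, 3), rg = 0, prevalence = 0.3,
                              env_cor = 0.5, binary = FALSE)
  co <- make_genotypes(3000, spec, seed = 21)
  co <- simulate_traits(co, arch0, seed = 22)
  expect_equal(max(abs(co$truth$genetic_values)), 0)
  expect_equal(cor(co$traits), cov2cor(arch0$C_E_liab),
               tolerance = 0.06, ignore_attr = TRUE)

  # realized prevalence within the binomial band
  arch_b <- trait_architecture(h2 = 0.1, prevalence = 0.2, traits = "t1")
  cob <- make_genotypes(10000, spec, seed = 23)
  cob <- simulate_traits(cob, arch_b, seed = 24)
  prev <- mean(cob$traits[, 1])
  expect_gt(prev, 0.18); expect_lt(prev, 0.22)
})

test_that("simulated genetic values reproduce the genetic covariance", {
  # independent SNPs so the only fluctuation is the effect-vector draw
  arch <- trait_architecture(h2 = rep(0.4, 4), rg = 0.7, prevalence = 0.5,
                             env_cor = 0, binary = FALSE)
  co <- make_genotypes(4000, block_spec(200, 10, within_block_r = 0), seed = 31)
  co <- simulate_traits(co, arch, seed = 32)
  Chat <- cov(co$truth$genetic_values)
  rel <- norm(Chat - arch$C_G_liab, "F") / norm(arch$C_G_liab, "F")
  expect_lt(rel, 0.10)
})

test_that("observed-scale transform has its closed forms and inverts liability_h2", {
  # K = 0.5 for both traits: factor phi(0)^2 / 0.25 = 0.63662
  arch <- trait_architecture(h2 = c(0.1, 0.1, 0.1), rg = 0.5, prevalence = 0.5)
  obs <- expected_observed_scale_cov(arch)
  expect_equal(obs[1, 2], arch$C_G_liab[1, 2] * 0.63662, tolerance = 1e-5)
  expect_equal(obs[1, 1], 0.1 * 0.63662, tolerance = 1e-5)

  # zero covariance maps to zero
  arch0 <- trait_architecture(h2 = c(0.1, 0.1, 0.1), rg = 0, prevalence = 0.3)
  expect_equal(expected_observed_scale_cov(arch0)[1, 2], 0)

  # round trip with the liability transform at the hip-pain prevalence
  K <- 0.0917
  archk <- trait_architecture(h2 = rep(0.08, 3), rg = 0.5, prevalence = K)
  h2_obs <- diag(expected_observed_scale_cov(archk))[1]
  expect_equal(unname(liability_h2(h2_obs, K)), 0.08, tolerance = 1e-10)
})

test_that("pain-like defaults give phenotypic correlations in the reported envelope", {
  arch <- pain_architecture()
  expect_equal(unname(arch$prevalence),
               c(0.179, 0.163, 0.092, 0.175))
  # n large enough that sampling noise (~0.007) cannot push a pair out of
  # the calibrated 0.21-0.24 band
  co <- make_genotypes(20000, block_spec(10, 10), seed = 41)
  co <- simulate_traits(co, arch, seed = 42)
  rp <- cor(co$traits)[upper.tri(diag(4))]
  expect_true(all(rp > 0.18 & rp < 0.28))
})
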