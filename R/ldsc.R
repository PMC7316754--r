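# Simplified LD Score regression.
#
# Univariate model:  E[chi2_j] = N * h2 * l_j / M + intercept
# Bivariate model:   E[z1_j z2_j] = sqrt(N1 N2) * cov_g * l_j / M + intercept
#
# Both are weighted least squares with a free intercept and a fixed two-pass
# weighting scheme (pass 1: 1 / (2 l_j^2); pass 2: inverse squared expected
# value from the pass-1 fit, times l_j).  Standard errors come from a
# delete-one-block jackknife over contiguous SNP blocks; the per-block
# regressions reuse the pass-2 weights.

#' Empirical LD scores from genotype dosages
#'
#' `l_j = 1 + sum_{k != j, |pos_k - pos_j| <= window} r2_adj(j, k)` with the
#' small-sample adjustment `r2_adj = r2 - (1 - r2) / (n - 2)`, which removes
#' the upward bias of squared sample correlations; the self term contributes
#' exactly 1.  Correlations are computed within chromosomes only.
#'
#' @param cohort a `"gip_cohort"` (or list with `dosages` and `variant_meta`).
#' @param window_bp window half-width in base pairs.
#' @return named numeric vector of LD scores (names = SNP ids).  Monomorphic
#'   SNPs get `l_j = 1` and are reported in the `"monomorphic"` attribute.
#' @export
ld_scores_empirical <- function(cohort, window_bp = 1e6) {
  X <- cohort$dosages
  meta <- cohort$variant_meta
  n <- nrow(X)
  if (n < 3) stop_("need at least 3 individuals for adjusted LD scores")
  l <- rep(1, ncol(X))
  names(l) <- meta$SNP
  mono_all <- character(0)
  for (chr in unique(meta$CHR)) {
    idx <- which(meta$CHR == chr)
    D <- X[, idx, drop = FALSE]
    sds <- apply(D, 2, sd)
    mono <- sds == 0
    if (any(mono)) mono_all <- c(mono_all, meta$SNP[idx[mono]])
    if (sum(!mono) < 2) next
    sub <- idx[!mono]
    r2 <- cor(X[, sub, drop = FALSE])^2
    r2a <- r2 - (1 - r2) / (n - 2)
    pos <- meta$POS[sub]
    mask <- abs(outer(pos, pos, "-")) <= window_bp
    diag(mask) <- FALSE
    l[sub] <- 1 + rowSums(r2a * mask)
  }
  attr(l, "monomorphic") <- mono_all
  l
}

# match an LD-score argument (named vector, data.frame(SNP, L2), or bare
# aligned vector) to a summary-statistics table
match_ld <- function(ld, ss) {
  if (is.data.frame(ld)) {
    nm <- toupper(names(ld))
    ld <- setNames(ld[[which(nm == "L2")[1]]], ld[[which(nm == "SNP")[1]]])
  }
  if (!is.null(names(ld))) {
    out <- unname(ld[ss$SNP])
    if (anyNA(out)) stop_("LD scores missing for %d SNPs", sum(is.na(out)))
    return(out)
  }
  if (length(ld) != nrow(ss)) stop_("unnamed LD score vector not aligned with sumstats")
  as.numeric(ld)
}

# weighted regression of y on x with intercept plus delete-one-block
# estimates, all from per-block accumulated sums
wls_block_fit <- function(x, y, w, block) {
  S <- rowsum(cbind(w, w * x, w * x^2, w * y, w * x * y), block)
  tot <- colSums(S)
  solve_line <- function(s) {
    den <- s[1] * s[3] - s[2]^2
    slope <- (s[1] * s[5] - s[2] * s[4]) / den
    c(slope = slope, intercept = (s[4] - slope * s[2]) / s[1])
  }
  full <- solve_line(tot)
  del <- t(apply(S, 1, function(s) solve_line(tot - s)))
  list(slope = full[1], intercept = full[2],
       slope_del = del[, 1], int_del = del[, 2])
}

jackknife_se <- function(theta_del) {
  g <- length(theta_del)
  sqrt((g - 1) / g * sum((theta_del - mean(theta_del))^2))
}

# pass-2 weights shared by the univariate and bivariate fits so that the
# bivariate fit of a table with itself reduces exactly to the univariate fit
ldsc_pass2_w <- function(ld, N, est, intercept, M) {
  est_c <- max(min(est, 2), -2)
  d <- pmax(intercept + N * est_c * ld / M, 0.05)
  1 / (2 * d^2 * ld)
}

contiguous_blocks <- function(m, n_blocks) {
  n_blocks <- max(2L, min(as.integer(n_blocks), m %/% 2L))
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

# large-effect outlier cap: SNPs with chi2 above max(80, 0.001 N) are
# excluded from the regression (single huge loci would otherwise dominate
# the fit and destabilize the intercept)
ldsc_chi2_cap <- function(N) max(80, 0.001 * N)

ldsc_core <- function(ld, yvals, N, M, n_blocks, type) {
  m <- length(yvals)
  if (m < 4) stop_("too few SNPs for LD score regression")
  if (sd(ld) == 0) stop_("LD scores have zero variance; slope not identifiable")
  if (n_blocks > m) stop_("more jackknife blocks than SNPs")
  block <- contiguous_blocks(m, n_blocks)
  w1 <- 1 / (2 * ld^2)
  f1 <- wls_block_fit(ld, yvals, w1, block)
  est1 <- unname(f1$slope) * M / N
  w2 <- ldsc_pass2_w(ld, N, est1, max(unname(f1$intercept), 0.1), M)
  f2 <- wls_block_fit(ld, yvals, w2, block)
  est <- unname(f2$slope) * M / N
  est_del <- unname(f2$slope_del) * M / N
  flag <- if (type == "h2" && (est < -0.5 || est > 1.5))
    "h2 estimate outside [-0.5, 1.5] guardrail" else NULL
  structure(list(type = type,
                 estimate = est,
                 se = jackknife_se(est_del),
                 intercept = unname(f2$intercept),
                 intercept_se = jackknife_se(f2$int_del),
                 delete_est = est_del,
                 delete_int = unname(f2$int_del),
                 n_blocks = max(block), M = M, N = N, n_snps = m,
                 flag = flag),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  lab <- if (x$type == "h2") "h2 (observed scale)" else "genetic covariance"
  cat(sprintf("LD score regression (%d SNPs, %d jackknife blocks)\n",
              x$n_snps, x$n_blocks))
  cat(sprintf("  %s: %.4f (SE %.4f)\n", lab, x$estimate, x$se))
  cat(sprintf("  intercept: %.4f (SE %.4f)\n", x$intercept, x$intercept_se))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

# drop rows that cannot enter the regression (monomorphic / non-finite)
ldsc_usable <- function(ss) {
  ok <- is.finite(ss$BETA) & is.finite(ss$SE) & ss$SE > 0
  if ("FLAG" %in% names(ss)) ok <- ok & (ss$FLAG == "" | is.na(ss$FLAG))
  ss[ok, , drop = FALSE]
}

#' Univariate LD Score regression
#'
#' Regresses per-SNP association chi-square statistics `(BETA/SE)^2` on LD
#' scores.  The slope times `M / N` estimates the observed-scale SNP
#' heritability; the free intercept captures residual confounding.  Negative
#' estimates are reported and flagged, never truncated.
#'
#' @param ss summary-statistics data frame (see [gwas_scan()]).
#' @param ld LD scores: named vector, `data.frame(SNP, L2)`, or a bare vector
#'   aligned with `ss`.
#' @param M number of SNPs the heritability refers to (defaults to the
#'   number used in the regression).
#' @param n_blocks number of jackknife blocks (clipped to at most half the
#'   SNP count).
#' @return an object of class `"ldsc_fit"`.
#' @export
ldsc_univariate <- function(ss, ld, M = NULL, n_blocks = 200) {
  ld <- match_ld(ld, ss)
  keep <- is.finite(ss$BETA) & is.finite(ss$SE) & ss$SE > 0
  ss <- ss[keep, , drop = FALSE]; ld <- ld[keep]
  chi2 <- (ss$BETA / ss$SE)^2
  N <- median(ss$N)
  M <- M %||% nrow(ss)
  cap <- chi2 <= ldsc_chi2_cap(N)
  ldsc_core(ld[cap], chi2[cap], N, M, n_blocks, "h2")
}

# align ss2 onto ss1 by SNP id, harmonizing alleles (swap -> sign flip);
# returns the aligned pair and the number of dropped mismatches
align_sumstats_pair <- function(ss1, ss2) {
  idx <- match(ss1$SNP, ss2$SNP)
  keep <- !is.na(idx)
  a <- ss1[keep, , drop = FALSE]
  b <- ss2[idx[keep], , drop = FALSE]
  same <- a$EA == b$EA & a$OA == b$OA
  swap <- a$EA == b$OA & a$OA == b$EA
  b$BETA[swap] <- -b$BETA[swap]
  if ("EAF" %in% names(b)) b$EAF[swap] <- 1 - b$EAF[swap]
  b$EA[swap] <- a$EA[swap]; b$OA[swap] <- a$OA[swap]
  ok <- same | swap
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("align_sumstats_pair: dropped %d SNPs with mismatched alleles", n_drop))
  list(ss1 = a[ok, , drop = FALSE], ss2 = b[ok, , drop = FALSE], dropped = n_drop)
}

#' Bivariate LD Score regression (genetic covariance)
#'
#' Regresses per-SNP z-score products on LD scores; the slope times
#' `M / sqrt(N1 N2)` estimates the genetic covariance of the two traits on
#' the analyzed scale.  The free intercept absorbs sample overlap (for fully
#' overlapping cohorts it is expected near the phenotypic correlation).
#' SNPs are matched on id and allele-aligned (an EA/OA swap flips the sign
#' of the second z-score; other allele mismatches are dropped with a
#' message).
#'
#' @inheritParams ldsc_univariate
#' @param ss1,ss2 summary-statistics data frames for the two traits.
#' @return an object of class `"ldsc_fit"`.
#' @export
ldsc_bivariate <- function(ss1, ss2, ld, M = NULL, n_blocks = 200) {
  ss1 <- ldsc_usable(ss1); ss2 <- ldsc_usable(ss2)
  al <- align_sumstats_pair(ss1, ss2)
  if (nrow(al$ss1) < 0.5 * max(nrow(ss1), nrow(ss2)))
    stop_("less than 50%% SNP overlap between the two tables")
  ld <- match_ld(ld, al$ss1)
  z1 <- al$ss1$BETA / al$ss1$SE
  z2 <- al$ss2$BETA / al$ss2$SE
  N <- sqrt(median(al$ss1$N) * median(al$ss2$N))
  M <- M %||% nrow(al$ss1)
  cap <- z1^2 <= ldsc_chi2_cap(N) & z2^2 <= ldsc_chi2_cap(N)
  ldsc_core(ld[cap], (z1 * z2)[cap], N, M, n_blocks, "gcov")
}

#' Assemble a genetic covariance matrix from per-trait summary statistics
#'
#' Runs all `T` univariate and `T (T - 1) / 2` bivariate LD score regressions
#' on a common, allele-aligned SNP set with the SAME contiguous jackknife
#' blocks, and assembles the joint block-jackknife sampling covariance `J` of
#' the `T (T + 1) / 2` unique matrix entries (half-vectorization order:
#' column-major lower triangle).
#'
#' @param ss_list named list of >= 3 summary-statistics data frames.
#' @param ld LD scores (named vector or `data.frame(SNP, L2)`).
#' @param M number of SNPs the estimates refer to (default: common SNP count).
#' @param n_blocks number of jackknife blocks.
#' @return an object of class `"genetic_cov"`: list with `C_G` (T x T,
#'   diagonal = observed-scale h2), `intercepts`, `SE` (entrywise jackknife
#'   SEs), `J`, `delete_values` (blocks x entries), `traits`, `M`,
#'   `n_blocks`.
#' @export
build_cov_matrix <- function(ss_list, ld, M = NULL, n_blocks = 200) {
  T_ <- length(ss_list)
  if (T_ < 3) stop_("the decomposition needs three or more traits")
  traits <- names(ss_list) %||% paste0("trait", seq_len(T_))
  if (is.null(names(ss_list))) names(ss_list) <- traits

  ss_list <- lapply(ss_list, ldsc_usable)
  common <- Reduce(intersect, lapply(ss_list, `[[`, "SNP"))
  if (length(common) < 4) stop_("too few common SNPs across traits")
  ref <- ss_list[[1]]
  ref <- ref[ref$SNP %in% common, , drop = FALSE]
  ref <- ref[order(ref$CHR, ref$POS), , drop = FALSE]
  aligned <- vector("list", T_); names(aligned) <- traits
  aligned[[1]] <- ref
  drop_snps <- character(0)
  for (t in 2:T_) {
    al <- align_sumstats_pair(ref, ss_list[[t]])
    if (al$dropped > 0)
      drop_snps <- union(drop_snps, setdiff(ref$SNP, al$ss1$SNP))
    aligned[[t]] <- al$ss2
  }
  if (length(drop_snps) > 0) {
    keepers <- !(ref$SNP %in% drop_snps)
    aligned <- lapply(aligned, function(s) s[s$SNP %in% ref$SNP[keepers], , drop = FALSE])
    ref <- aligned[[1]]
  }
  # remove large-chi2 outliers jointly, so every pairwise fit uses the same
  # SNP set and the same jackknife blocks
  caps <- lapply(aligned, function(s) {
    (s$BETA / s$SE)^2 <= ldsc_chi2_cap(median(s$N))
  })
  cap_all <- Reduce(`&`, caps)
  if (!all(cap_all)) {
    aligned <- lapply(aligned, function(s) s[cap_all, , drop = FALSE])
    ref <- aligned[[1]]
  }
  m <- nrow(ref)
  M <- M %||% m

  p <- T_ * (T_ + 1) / 2
  fits <- vector("list", p)
  labels <- character(p)
  pos <- 1
  for (j in seq_len(T_)) {
    for (i in j:T_) {
      fits[[pos]] <- tryCatch(
        if (i == j) ldsc_univariate(aligned[[i]], ld, M = M, n_blocks = n_blocks)
        else ldsc_bivariate(aligned[[i]], aligned[[j]], ld, M = M, n_blocks = n_blocks),
        error = function(e) stop_("LDSC fit failed for pair (%s, %s): %s",
                                  traits[i], traits[j], conditionMessage(e)))
      labels[pos] <- paste(traits[i], traits[j], sep = ":")
      pos <- pos + 1
    }
  }

  g <- fits[[1]]$n_blocks
  D <- vapply(fits, function(f) f$delete_est, numeric(g))
  colnames(D) <- labels
  Dc <- sweep(D, 2, colMeans(D))
  J <- (g - 1) / g * crossprod(Dc)

  C_G <- matrix(0, T_, T_, dimnames = list(traits, traits))
  SE <- intercepts <- C_G
  pos <- 1
  for (j in seq_len(T_)) {
    for (i in j:T_) {
      C_G[i, j] <- C_G[j, i] <- fits[[pos]]$estimate
      SE[i, j] <- SE[j, i] <- fits[[pos]]$se
      intercepts[i, j] <- intercepts[j, i] <- fits[[pos]]$intercept
      pos <- pos + 1
    }
  }

  structure(list(C_G = C_G, intercepts = intercepts, SE = SE, J = J,
                 delete_values = D, traits = traits, M = M,
                 n_blocks = g, n_snps = m, fits = setNames(fits, labels)),
            class = "genetic_cov")
}

#' @export
print.genetic_cov <- function(x, digits = 4, ...) {
  cat(sprintf("Genetic covariance matrix: %d traits, %d SNPs, %d jackknife blocks\n",
              length(x$traits), x$n_snps, x$n_blocks))
  cat("C_G (diagonal = observed-scale h2):\n")
  print(round(x$C_G, digits))
  cat("entrywise jackknife SE:\n")
  print(round(x$SE, digits))
  invisible(x)
}

#' Genetic correlations with jackknife standard errors
#'
#' `r_g(t, s) = C_G[t, s] / sqrt(C_G[t, t] * C_G[s, s])`, with SEs from the
#' joint delete-one-block replicates stored in a [build_cov_matrix()] result.
#' Delete-block replicates with non-positive heritability are dropped from
#' the SE computation (with a warning) since the correlation is undefined
#' there; values beyond `[-1.05, 1.05]` are flagged.
#'
#' @param est a `"genetic_cov"` object.
#' @return list with `rg` and `se` matrices.
#' @export
rg_matrix <- function(est) {
  stopifnot(inherits(est, "genetic_cov"))
  T_ <- length(est$traits)
  h2 <- diag(est$C_G)
  if (any(h2 <= 0))
    warn_("rg_matrix: non-positive heritability for %s; correlations involving it are NA",
          paste(est$traits[h2 <= 0], collapse = ", "))
  rg <- est$C_G / sqrt(ifelse(h2 > 0, h2, NA_real_) %o% ifelse(h2 > 0, h2, NA_real_))
  se <- matrix(0, T_, T_, dimnames = dimnames(est$C_G))
  D <- est$delete_values
  lab <- function(i, j) paste(est$traits[max(i, j)], est$traits[min(i, j)], sep = ":")
  dropped <- 0L
  for (j in seq_len(T_ - 1)) for (i in (j + 1):T_) {
    hi <- D[, lab(i, i)]; hj <- D[, lab(j, j)]; cij <- D[, lab(i, j)]
    ok <- hi > 0 & hj > 0
    dropped <- dropped + sum(!ok)
    r_del <- cij[ok] / sqrt(hi[ok] * hj[ok])
    se[i, j] <- se[j, i] <- if (length(r_del) >= 2) jackknife_se(r_del) else NA_real_
  }
  if (dropped > 0)
    warn_("rg_matrix: %d delete-block replicates with non-positive h2 dropped from SEs", dropped)
  if (any(abs(rg[upper.tri(rg)]) > 1.05, na.rm = TRUE))
    warn_("genetic correlation beyond [-1.05, 1.05]; estimate is noise-dominated")
  list(rg = rg, se = se)
}

#' Observed-scale to liability-scale heritability
#'
#' `h2_liab = h2_obs * K^2 (1 - K)^2 / (P (1 - P) * phi(z)^2)` with
#' `z = qnorm(1 - K)`, `K` the population prevalence and `P` the sample case
#' fraction.  For a population cohort (`P = K`, the default) this reduces to
#' `h2_obs * K (1 - K) / phi(z)^2`.
#'
#' @param h2_obs observed-scale (0/1 trait) SNP heritability.
#' @param K population prevalence in `(0, 1)`.
#' @param P sample case proportion in `(0, 1)`; defaults to `K`.
#' @return liability-scale heritability.
#' @export
liability_h2 <- function(h2_obs, K, P = K) {
  if (any(K <= 0 | K >= 1) || any(P <= 0 | P >= 1))
    stop_("K and P must lie strictly inside (0, 1)")
  z <- qnorm(1 - K)
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(z)^2)
}
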