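# GIP-level GWAS: individual-level and summary-level routes, plus predicted
# phenotypic correlations and heritability of the components.

#' GIP phenotype scores from a trait panel
#'
#' Standardizes each trait column within the cohort (n - 1 denominator) and
#' applies the fitted transformation coefficients.  Trait names must match
#' the model; columns are reordered if needed.
#'
#' @param traits `n x T` matrix or data frame of trait values.
#' @param model a fitted `"gip"` model.
#' @return `n x T` matrix of GIP scores (columns `GIP1..GIPT`).
#' @export
gip_scores <- function(traits, model) {
  stopifnot(inherits(model, "gip"))
  Y <- as.matrix(traits)
  if (is.null(colnames(Y))) {
    if (ncol(Y) != length(model$traits))
      stop_("trait panel has %d columns; model expects %d", ncol(Y), length(model$traits))
    colnames(Y) <- model$traits
  }
  if (!setequal(colnames(Y), model$traits))
    stop_("trait names do not match the model: %s",
          paste(setdiff(model$traits, colnames(Y)), collapse = ", "))
  Y <- Y[, model$traits, drop = FALSE]
  Ys <- apply(Y, 2, standardize, name = "trait")
  scores <- Ys %*% model$loadings
  colnames(scores) <- colnames(model$loadings)
  scores
}

#' GIP GWAS from individual-level data
#'
#' Builds GIP scores from the cohort's traits (with the discovery-fitted
#' loadings) and runs [gwas_scan()] on each component with the same
#' covariates as the trait GWAS.
#'
#' @param cohort a `"gip_cohort"` with traits filled.
#' @param model a fitted `"gip"` model.
#' @param covariates optional covariate matrix (see [gwas_scan()]).
#' @return named list of summary-statistics data frames, one per GIP.
#' @export
gip_gwas_individual <- function(cohort, model, covariates = NULL) {
  scores <- gip_scores(cohort$traits, model)
  out <- lapply(seq_len(ncol(scores)), function(k)
    gwas_scan(cohort, scores[, k], covariates = covariates))
  names(out) <- colnames(scores)
  out
}

#' GIP GWAS from per-trait summary statistics
#'
#' Linear-combination route for cohorts where only per-trait summary
#' statistics exist.  All tables must come from the same cohort, with effect
#' sizes on the standardized-phenotype scale (run [gwas_scan()] with
#' `standardize_trait = TRUE`).  For GIP k at SNP j:
#' `BETA = sum_t A[t, k] * BETA_t(j)` and
#' `SE = sqrt(sum_{t,s} A[t, k] A[s, k] * C_P[t, s] * SE_t(j) * SE_s(j))`,
#' using the standard full-overlap approximation
#' `cov(beta_t, beta_s) = C_P[t, s] * SE_t * SE_s`; P from the normal law.
#'
#' @param ss_list named list of per-trait summary statistics (names = model
#'   traits).
#' @param model a fitted `"gip"` model.
#' @param C_P `T x T` phenotypic correlation matrix of the traits.
#' @param N optional effective sample size override.
#' @return named list of summary-statistics data frames, one per GIP.
#' @export
gip_gwas_summary <- function(ss_list, model, C_P, N = NULL) {
  stopifnot(inherits(model, "gip"))
  traits <- model$traits
  if (!setequal(names(ss_list), traits))
    stop_("names of ss_list must match the model traits")
  ss_list <- ss_list[traits]
  C_P <- as.matrix(C_P)

  ref <- ss_list[[1]]
  aligned <- vector("list", length(traits)); names(aligned) <- traits
  aligned[[1]] <- ref
  for (t in 2:length(traits)) {
    al <- align_sumstats_pair(ref, ss_list[[t]])
    if (nrow(al$ss1) < nrow(ref)) {
      dropped <- nrow(ref) - nrow(al$ss1)
      message(sprintf("gip_gwas_summary: dropped %d SNPs absent or misaligned in %s",
                      dropped, traits[t]))
      ref <- al$ss1
      aligned <- lapply(aligned[seq_len(t - 1)], function(s)
        s[s$SNP %in% ref$SNP, , drop = FALSE])
      aligned[[traits[t]]] <- al$ss2
    } else aligned[[t]] <- al$ss2
  }
  B <- do.call(cbind, lapply(aligned, `[[`, "BETA"))
  S <- do.call(cbind, lapply(aligned, `[[`, "SE"))
  Ns <- do.call(cbind, lapply(aligned, `[[`, "N"))
  if (diff(range(colMeans(Ns))) > 0.01 * min(colMeans(Ns)))
    warn_("per-trait sample sizes differ by more than 1%%; using the per-SNP minimum")
  N_j <- if (!is.null(N)) rep(N, nrow(ref)) else apply(Ns, 1, min)

  A <- model$loadings
  out <- lapply(seq_len(ncol(A)), function(k) {
    a <- A[, k]
    beta <- as.vector(B %*% a)
    W <- sweep(S, 2, a, "*")
    se <- sqrt(rowSums((W %*% C_P) * W))
    ss <- ref
    ss$BETA <- beta
    ss$SE <- se
    ss$P <- p_from_z(beta / se)
    ss$N <- N_j
    if ("FLAG" %in% names(ss)) ss$FLAG <- ""
    ss
  })
  names(out) <- colnames(A)
  out
}

#' Predicted phenotypic correlations of GIPs
#'
#' Since GIP scores are fixed linear combinations of the standardized traits,
#' their phenotypic covariance is `t(A) %*% C_P %*% A`; correlations follow
#' by normalizing with the diagonal, and the trait x GIP correlation is
#' `(C_P %*% a_k)[t] / sqrt(a_k' C_P a_k)` (traits standardized).
#'
#' @param model a fitted `"gip"` model.
#' @param C_P phenotypic correlation matrix of the traits.
#' @return list with `gip_corr` (GIP x GIP), `trait_gip_corr` (trait x GIP)
#'   and `gip_var` (phenotypic variances of the GIP scores).
#' @export
predict_gip_pheno_corr <- function(model, C_P) {
  stopifnot(inherits(model, "gip"))
  C_P <- as.matrix(C_P)
  if (max(abs(diag(C_P) - 1)) > 1e-8) stop_("C_P must have unit diagonal")
  if (!is_psd(C_P)) warn_("C_P is not positive semidefinite; proceeding")
  A <- model$loadings
  G <- t(A) %*% C_P %*% A
  gv <- diag(G)
  gip_corr <- G / sqrt(gv %o% gv)
  trait_gip <- (C_P %*% A) / rep(sqrt(gv), each = nrow(A))
  dimnames(trait_gip) <- dimnames(A)
  list(gip_corr = gip_corr, trait_gip_corr = trait_gip, gip_var = gv)
}

#' Observed-scale heritability of each GIP
#'
#' The genetic variance of GIP k is its eigenvalue; its phenotypic variance
#' is `a_k' C_P a_k` (standardized traits), so
#' `h2_GIPk = lambda_k / (a_k' C_P a_k)`.
#'
#' @param model a fitted `"gip"` model.
#' @param C_P phenotypic correlation matrix of the traits.
#' @return named vector of per-GIP observed-scale heritabilities.
#' @export
gip_h2 <- function(model, C_P) {
  stopifnot(inherits(model, "gip"))
  A <- model$loadings
  pv <- diag(t(A) %*% as.matrix(C_P) %*% A)
  if (any(pv <= 0)) stop_("non-positive GIP phenotypic variance")
  setNames(model$eigenvalues / pv, colnames(A))
}
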