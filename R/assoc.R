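# Per-trait association scans and variant QC.

#' Variant QC thresholds
#'
#' All filters are strict inequalities: a variant survives only if its value
#' exceeds the threshold.  Defaults follow common biobank-scale practice for
#' European-ancestry samples (MAF > 2e-4, imputation INFO > 0.7, call rates
#' > 0.98).
#'
#' @param maf_min minimum minor allele frequency.
#' @param info_min minimum imputation quality score.
#' @param call_rate_min minimum variant/individual call rate.
#' @return an object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(maf_min = 2e-4, info_min = 0.7, call_rate_min = 0.98) {
  v <- c(maf_min = maf_min, info_min = info_min, call_rate_min = call_rate_min)
  if (any(v < 0 | v > 1)) stop_("QC thresholds must lie in [0, 1]")
  structure(as.list(v), class = "qc_thresholds")
}

#' Filter variants on MAF, imputation quality and call rate
#'
#' @param variants data frame with a `MAF` column and optional `INFO` and
#'   `CALL_RATE` columns.  A missing `INFO` (or `CALL_RATE`) column, or `NA`
#'   entries in it, are treated as passing and counted in the log.
#' @param thr a [qc_thresholds()].
#' @return list with `kept` (surviving rows), `excluded` (dropped rows) and
#'   `log` (named counts of failures per criterion, plus `missing_info`).
#' @export
qc_filter <- function(variants, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  if (nrow(variants) == 0) {
    warn_("qc_filter: empty variant table")
    return(list(kept = variants, excluded = variants,
                log = c(maf = 0L, info = 0L, call_rate = 0L, missing_info = 0L)))
  }
  if (!"MAF" %in% names(variants)) stop_("variants must have a MAF column")
  maf_ok <- variants$MAF > thr$maf_min
  if ("INFO" %in% names(variants)) {
    info <- variants$INFO
    missing_info <- sum(is.na(info))
    info_ok <- is.na(info) | info > thr$info_min
  } else {
    missing_info <- nrow(variants)
    info_ok <- rep(TRUE, nrow(variants))
  }
  if ("CALL_RATE" %in% names(variants)) {
    cr <- variants$CALL_RATE
    cr_ok <- is.na(cr) | cr > thr$call_rate_min
  } else {
    cr_ok <- rep(TRUE, nrow(variants))
  }
  keep <- maf_ok & info_ok & cr_ok
  list(kept = variants[keep, , drop = FALSE],
       excluded = variants[!keep, , drop = FALSE],
       log = c(maf = sum(!maf_ok), info = sum(!info_ok),
               call_rate = sum(!cr_ok), missing_info = missing_info))
}

#' Standardize a vector to zero mean, unit variance
#'
#' Uses the `n - 1` denominator.  This is the scale convention used for all
#' GIP weighting: traits are standardized within the cohort being analyzed
#' before applying transformation coefficients.
#'
#' @param x numeric vector of length >= 2.
#' @param name label used in the error message for constant input.
#' @return standardized numeric vector.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) stop_("standardize: need at least 2 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop_("standardize: '%s' has zero variance", name)
  (x - mean(x)) / s
}

#' Covariate-adjusted single-SNP association scan
#'
#' For each SNP, the phenotype and the dosage are residualized on the
#' intercept and the covariates, and the residual phenotype is regressed on
#' the residual dosage (equivalent to the SNP coefficient in the joint OLS
#' fit).  Binary traits are analyzed on the 0/1 scale by linear regression,
#' which keeps the observed-scale heritability algebra intact.  P-values use
#' the normal approximation when the residual degrees of freedom
#' `n - C - 2 >= 100`, and the t law otherwise.
#'
#' Monomorphic SNPs are emitted with `BETA = 0`, `SE = Inf`, `P = 1`; a
#' perfect fit (zero residual variance) yields `SE = 0`, `P = 0`.  Both are
#' flagged in the `FLAG` column.
#'
#' @param cohort a `"gip_cohort"`, or any list with `dosages` and
#'   `variant_meta`.
#' @param phenotype a column name of `cohort$traits` or a numeric vector of
#'   length `n`.
#' @param covariates optional `n x C` numeric matrix/data frame (no
#'   intercept column; one is added internally).
#' @param standardize_trait if `TRUE` the phenotype is standardized first, so
#'   effect sizes are on the standardized-phenotype scale (required when the
#'   summary statistics will feed the summary-level GIP GWAS route).
#' @return a summary-statistics data frame with columns `SNP, CHR, POS, EA,
#'   OA, EAF, BETA, SE, P, N, FLAG`.
#' @export
gwas_scan <- function(cohort, phenotype, covariates = NULL,
                      standardize_trait = FALSE) {
  X <- cohort$dosages
  n <- nrow(X)
  y <- if (is.character(phenotype)) {
    if (is.null(cohort$traits) || !phenotype %in% colnames(cohort$traits))
      stop_("phenotype '%s' not found in cohort traits", phenotype)
    cohort$traits[, phenotype]
  } else as.numeric(phenotype)
  if (length(y) != n) stop_("phenotype length does not match cohort size")
  if (standardize_trait) y <- standardize(y, "phenotype")

  if (!is.null(covariates)) {
    Cmat <- as.matrix(covariates)
    if (nrow(Cmat) != n) stop_("covariates not row-aligned with dosages")
    D <- cbind(1, Cmat)
    if (qr(D)$rank < ncol(D)) stop_("covariate matrix is rank deficient")
    nc <- ncol(Cmat)
  } else {
    D <- matrix(1, n, 1)
    nc <- 0L
  }
  qrD <- qr(D)
  yr <- qr.resid(qrD, y)
  Xr <- qr.resid(qrD, X)

  sxx <- colSums(Xr^2)
  sxy <- as.vector(crossprod(Xr, yr))
  syy <- sum(yr^2)
  df <- n - nc - 2L
  if (df < 1) stop_("not enough residual degrees of freedom (n too small)")

  mono <- sxx < n * 1e-12
  beta <- ifelse(mono, 0, sxy / sxx)
  rss <- pmax(syy - beta * sxy, 0)
  sigma2 <- rss / df
  se <- ifelse(mono, Inf, sqrt(sigma2 / pmax(sxx, .Machine$double.eps)))
  z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  p <- if (df >= 100) p_from_z(z) else 2 * pt(-abs(z), df)
  p[mono] <- 1
  p[is.finite(beta) & se == 0] <- 0

  flag <- character(length(beta))
  flag[mono] <- "monomorphic"
  flag[!mono & se == 0] <- "degenerate"

  meta <- cohort$variant_meta
  out <- data.frame(
    SNP = meta$SNP, CHR = meta$CHR, POS = meta$POS,
    EA = meta$A1, OA = meta$A2,
    EAF = colMeans(X) / 2,
    BETA = beta, SE = se, P = p, N = n, FLAG = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}
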