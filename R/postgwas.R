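# Post-GWAS processing: genomic-control correction via the LDSC intercept,
# fixed-effects meta-analysis, distance-based clumping, and the
# discovery -> replication decision rule.

#' Genomic-control correction using an LD score regression intercept
#'
#' Divides each association chi-square by the intercept and converts back to
#' a p-value: `chi2_GC = (BETA/SE)^2 / intercept`.  Effect sizes are left
#' unchanged; the standard error is rescaled by `sqrt(intercept)` so that
#' `(BETA/SE_GC)^2 = chi2_GC`.  The corrected p-value is computed in log
#' space, so it does not underflow down to `P ~ 1e-300`; the `LOG10P_GC`
#' column carries `-log10(P_GC)` exactly even beyond that.
#'
#' @param ss summary-statistics data frame.
#' @param intercept positive LDSC intercept of the scan being corrected.
#' @return `ss` with added columns `P_GC`, `SE_GC`, `LOG10P_GC`.
#' @export
gc_correct <- function(ss, intercept) {
  if (length(intercept) != 1 || !is.finite(intercept) || intercept <= 0)
    stop_("intercept must be a single positive number")
  chi2 <- (ss$BETA / ss$SE)^2 / intercept
  logp <- pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  ss$P_GC <- exp(logp)
  ss$SE_GC <- ss$SE * sqrt(intercept)
  ss$LOG10P_GC <- -logp / log(10)
  ss
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort summary statistics with weights `w_i = 1 / SE_i^2`:
#' `BETA = sum(w_i BETA_i) / sum(w_i)`, `SE = 1 / sqrt(sum(w_i))`, P from
#' the normal law, `N = sum(N_i)`.  Records are matched on `(CHR, POS)` and
#' allele-aligned to the first cohort in which each SNP appears (an EA/OA
#' swap flips the effect sign and the EAF; other allele pairs are dropped
#' with a message).  SNPs present in a subset of cohorts are meta-analyzed
#' over that subset.
#'
#' @param ss_list list of summary-statistics data frames (>= 1).
#' @return a single meta-analyzed summary-statistics data frame.
#' @export
ivw_meta <- function(ss_list) {
  if (length(ss_list) == 0) stop_("need at least one cohort")
  if (length(ss_list) == 1) return(ss_list[[1]])
  usable <- lapply(ss_list, function(s) s[is.finite(s$SE) & s$SE > 0, , drop = FALSE])

  key <- function(s) paste(s$CHR, s$POS, sep = ":")
  ref <- NULL
  for (s in usable) {
    k <- key(s)
    new <- if (is.null(ref)) rep(TRUE, nrow(s)) else !(k %in% key(ref))
    ref <- rbind(ref, s[new, c("SNP", "CHR", "POS", "EA", "OA"), drop = FALSE])
  }
  ref <- ref[order(ref$CHR, ref$POS), , drop = FALSE]
  rk <- key(ref)
  m <- nrow(ref)
  sw <- swb <- sn <- swf <- numeric(m)
  dropped <- 0L
  for (s in usable) {
    idx <- match(key(s), rk)
    same <- s$EA == ref$EA[idx] & s$OA == ref$OA[idx]
    swap <- s$EA == ref$OA[idx] & s$OA == ref$EA[idx]
    beta <- ifelse(swap, -s$BETA, s$BETA)
    eaf <- if ("EAF" %in% names(s)) ifelse(swap, 1 - s$EAF, s$EAF) else rep(NA_real_, nrow(s))
    ok <- same | swap
    dropped <- dropped + sum(!ok)
    i <- idx[ok]
    w <- 1 / s$SE[ok]^2
    sw[i] <- sw[i] + w
    swb[i] <- swb[i] + w * beta[ok]
    sn[i] <- sn[i] + s$N[ok]
    swf[i] <- swf[i] + s$N[ok] * eaf[ok]
  }
  if (dropped > 0)
    message(sprintf("ivw_meta: dropped %d records with mismatched alleles", dropped))
  if (all(sw == 0)) stop_("no SNPs could be meta-analyzed")
  beta <- swb / sw
  se <- 1 / sqrt(sw)
  data.frame(ref,
             EAF = swf / sn,
             BETA = beta, SE = se, P = p_from_z(beta / se), N = sn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Distance-based locus clumping
#'
#' Iteratively selects the most significant SNP below `threshold`, forms a
#' locus of `lead position +/- window`, removes every sub-threshold SNP
#' inside it, and repeats.  Ties in P are broken deterministically by
#' `(CHR, POS)`.  Loci are pairwise non-overlapping and their members
#' partition the sub-threshold SNPs.
#'
#' @param ss summary-statistics data frame.
#' @param threshold significance threshold in `(0, 1)`.
#' @param window locus half-width in base pairs (default 250 kb).
#' @param p_col which p-value column to clump on (e.g. `"P_GC"`).
#' @return data frame of lead-SNP records with `START`, `END`, `N_SNPS`
#'   columns; zero rows when nothing passes.
#' @export
clump <- function(ss, threshold, window = 250000, p_col = "P") {
  if (threshold <= 0 || threshold >= 1) stop_("threshold must be in (0, 1)")
  if (!p_col %in% names(ss)) stop_("column '%s' not found", p_col)
  cand <- ss[ss[[p_col]] < threshold, , drop = FALSE]
  cand <- cand[order(cand[[p_col]], cand$CHR, cand$POS), , drop = FALSE]
  loci <- list()
  while (nrow(cand) > 0) {
    lead <- cand[1, , drop = FALSE]
    inside <- cand$CHR == lead$CHR & abs(cand$POS - lead$POS) <= window
    lead$START <- lead$POS - window
    lead$END <- lead$POS + window
    lead$N_SNPS <- sum(inside)
    loci[[length(loci) + 1]] <- lead
    cand <- cand[!inside, , drop = FALSE]
  }
  if (length(loci) == 0) {
    out <- ss[0, , drop = FALSE]
    out$START <- integer(0); out$END <- integer(0); out$N_SNPS <- integer(0)
    return(out)
  }
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Bonferroni study threshold
#'
#' `base / n`: e.g. the genome-wide threshold 5e-8 divided by the number of
#' phenotypes tested, or a generic alpha divided by a test count.
#'
#' @param n number of phenotypes/tests (>= 1).
#' @param base the per-test significance level (default genome-wide 5e-8).
#' @return the corrected threshold.
#' @examples
#' study_threshold(4)            # 1.25e-8 for four GIPs
#' study_threshold(6 * 2244, base = 0.05)
#' @export
study_threshold <- function(n, base = 5e-8) {
  if (length(n) != 1 || n < 1) stop_("n must be a positive count")
  base / n
}

#' Discovery to replication decision procedure
#'
#' The replication threshold is `alpha` divided by the TOTAL number of
#' discovery loci (across all phenotypes).  A locus is replicated when its
#' lead SNP reaches that threshold in the replication meta-analysis AND the
#' effect direction agrees with discovery.  Lead SNPs missing from the
#' replication data get the verdict `"untested"`.
#'
#' @param disc_loci data frame of discovery loci (from [clump()]), with a
#'   `PHENOTYPE` column when loci from several scans are pooled.
#' @param repl_meta replication meta-analysis: a single summary-statistics
#'   data frame, or a named list keyed by phenotype.
#' @param alpha family-wise error rate (default 0.05).
#' @return a `"replication_report"` data frame: per locus, the discovery
#'   effect, the replication effect, the threshold used, sign consistency
#'   and the verdict.
#' @export
replication_gate <- function(disc_loci, repl_meta, alpha = 0.05) {
  n_loci <- nrow(disc_loci)
  if (n_loci == 0) stop_("zero discovery loci; nothing to replicate")
  threshold <- alpha / n_loci
  get_tab <- function(ph) {
    if (is.data.frame(repl_meta)) repl_meta
    else repl_meta[[ph]] %||% stop_("no replication table for phenotype '%s'", ph)
  }
  rows <- lapply(seq_len(n_loci), function(i) {
    loc <- disc_loci[i, ]
    ph <- if ("PHENOTYPE" %in% names(disc_loci)) loc$PHENOTYPE else NA_character_
    tab <- get_tab(ph)
    j <- which(tab$CHR == loc$CHR & tab$POS == loc$POS)
    out <- data.frame(PHENOTYPE = ph, SNP = loc$SNP, CHR = loc$CHR, POS = loc$POS,
                      BETA_DISC = loc$BETA, SE_DISC = loc$SE,
                      P_DISC = loc$P,
                      P_DISC_GC = if ("P_GC" %in% names(loc)) loc$P_GC else NA_real_,
                      BETA_REPL = NA_real_, SE_REPL = NA_real_,
                      P_REPL = NA_real_, N_REPL = NA_real_,
                      THRESHOLD = threshold, SIGN_CONSISTENT = NA,
                      VERDICT = "untested", stringsAsFactors = FALSE)
    if (length(j) >= 1) {
      r <- tab[j[1], ]
      flip <- r$EA == loc$OA && r$OA == loc$EA
      b <- if (flip) -r$BETA else r$BETA
      out$BETA_REPL <- b; out$SE_REPL <- r$SE
      out$P_REPL <- r$P; out$N_REPL <- r$N
      out$SIGN_CONSISTENT <- sign(b) == sign(loc$BETA)
      out$VERDICT <- if (r$P < threshold && out$SIGN_CONSISTENT)
        "replicated" else "not_replicated"
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("replication_report", class(out))
  out
}
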