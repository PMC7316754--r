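# Reading and writing summary-statistics tables and labeled matrices.
# One flat TSV dialect throughout (METAL/LDSC-adjacent), for diffability.

sumstats_synonyms <- list(
  SNP = c("SNP", "RSID", "ID", "MARKERNAME", "MARKER"),
  CHR = c("CHR", "CHROM", "CHROMOSOME"),
  POS = c("POS", "BP", "POSITION", "BASE_PAIR_LOCATION"),
  EA  = c("EA", "A1", "EFFECT_ALLELE", "ALT"),
  OA  = c("OA", "A2", "OTHER_ALLELE", "REF", "NON_EFFECT_ALLELE"),
  EAF = c("EAF", "FREQ", "AF", "A1FREQ", "EFFECT_ALLELE_FREQUENCY"),
  BETA = c("BETA", "B", "EFFECT", "ES"),
  SE  = c("SE", "STDERR", "STANDARD_ERROR"),
  P   = c("P", "PVAL", "PVALUE", "P_VALUE"),
  N   = c("N", "NOBS", "SAMPLE_SIZE"),
  INFO = c("INFO", "IMPUTATION_QUALITY", "RSQ")
)

#' Read a summary-statistics TSV
#'
#' Header matching is case-insensitive and tolerant to column reordering and
#' the common aliases (A1/A2, BP, PVAL, FREQ, ...).  Mandatory columns are
#' SNP, EA, OA, BETA, SE.  A missing or invalid P is recomputed from
#' `BETA/SE` under the normal law.  Rows with non-positive or non-finite SE
#' are rejected and logged with their line numbers; duplicate
#' `(CHR, POS, EA, OA)` keys (or duplicate SNP ids when positions are
#' absent) are an error.
#'
#' @param path path to a tab-separated file with a header.
#' @return a validated summary-statistics data frame.
#' @export
read_sumstats <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  up <- toupper(names(raw))
  out <- list()
  for (std in names(sumstats_synonyms)) {
    hit <- which(up %in% sumstats_synonyms[[std]])
    if (length(hit) >= 1) out[[std]] <- raw[[hit[1]]]
  }
  mandatory <- c("SNP", "EA", "OA", "BETA", "SE")
  missing_cols <- setdiff(mandatory, names(out))
  if (length(missing_cols) > 0)
    stop_("missing mandatory columns in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  bad <- !is.finite(out$SE) | out$SE <= 0 | !is.finite(out$BETA)
  if (any(bad)) {
    message(sprintf("read_sumstats: rejected %d rows with invalid BETA/SE (lines %s)",
                    sum(bad), paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) stop_("no valid rows in %s", path)

  if (is.null(out[["P"]])) {
    out$P <- p_from_z(out$BETA / out$SE)
  } else {
    bad_p <- !is.finite(out$P) | out$P <= 0 | out$P > 1
    if (any(bad_p)) {
      message(sprintf("read_sumstats: recomputed %d invalid P values from BETA/SE", sum(bad_p)))
      out$P[bad_p] <- p_from_z(out$BETA[bad_p] / out$SE[bad_p])
    }
  }
  key <- if (!is.null(out$CHR) && !is.null(out$POS))
    paste(out$CHR, out$POS, out$EA, out$OA) else out$SNP
  if (anyDuplicated(key))
    stop_("duplicate variant keys in %s (e.g. %s)", path, key[duplicated(key)][1])
  rownames(out) <- NULL
  out
}

#' Write a summary-statistics TSV
#'
#' Tab-separated with header; P (and P_GC when present) are written in
#' scientific notation with 4 significant digits, other numerics at full
#' precision.
#'
#' @param ss summary-statistics data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- ss
  for (col in intersect(c("P", "P_GC"), names(out)))
    out[[col]] <- formatC(out[[col]], format = "e", digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labeled square matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(NAME = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square matrix written by [write_matrix_tsv()]
#' @param path input path.
#' @return a matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
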