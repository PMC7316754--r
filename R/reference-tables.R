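# Published reference tables for four chronic musculoskeletal pain GIPs
# (back, neck/shoulder, hip and knee pain in a large UK population biobank;
# discovery N = 265,000 of European ancestry, replication meta-analysis
# N = 191,580).  Used as worked examples and as fixed inputs for the
# genomic-control and replication arithmetic.

#' Published lead SNPs for chronic musculoskeletal pain GIPs
#'
#' The nine discovery-significant loci of the four-trait chronic pain GIP
#' analysis: per locus, the GIP it is associated with, the lead SNP, GRCh37
#' coordinates, reference/effect alleles, discovery effect size, standard
#' error, raw and genomic-control-corrected p-values (intercepts 1.016,
#' 1.001, 1.013, 1.021 for GIP1-4), effect allele frequency (%), and the
#' replication meta-analysis results.  Six loci replicated at the Bonferroni
#' threshold 0.05/9.
#'
#' @return a data frame with one row per discovery locus.
#' @export
chronic_pain_gip_loci <- function() {
  data.frame(
    GIP  = c("GIP2", "GIP1", "GIP1", "GIP1", "GIP1", "GIP1", "GIP2", "GIP2", "GIP1"),
    SNP  = c("rs143384", "rs7628207", "rs13107325", "rs3737240", "rs73581580",
             "rs12705966", "rs4985445", "rs548227718", "rs111368900"),
    CHR  = c(20L, 3L, 4L, 1L, 9L, 7L, 16L, 5L, 1L),
    POS  = c(34025756L, 49754970L, 103188709L, 150483355L, 140251458L,
             114248851L, 69867835L, 175902724L, 53084695L),
    OA   = c("C", "T", "T", "T", "G", "G", "G", "G", "G"),
    EA   = c("T", "C", "C", "C", "A", "A", "A", "A", "A"),
    GENE = c("GDF5", "AMIGO3", "SLC39A8", "ECM1", "EXD3", "FOXP2", "WWP2",
             "FAF2", "GPX7"),
    BETA = c(-0.020, -0.023, -0.032, 0.017, 0.025, 0.018, 0.017, -0.283, 0.242),
    SE   = c(0.003, 0.004, 0.005, 0.003, 0.004, 0.003, 0.003, 0.048, 0.041),
    P    = c(4.87e-13, 1.71e-10, 8.78e-10, 2.01e-09, 3.89e-09, 5.71e-09,
             1.56e-09, 3.02e-09, 5.01e-09),
    P_GC = c(7.40e-13, 2.37e-10, 1.19e-09, 2.69e-09, 5.15e-09, 7.52e-09,
             2.09e-09, 4.01e-09, 6.60e-09),
    EAF  = c(59.8, 82.3, 92.6, 60.4, 12.4, 66.7, 54.3, 0.1, 0.2),
    BETA_REPL = c(-0.022, -0.012, -0.035, 0.010, 0.030, 0.012, 0.007, 0.096, 0.089),
    SE_REPL   = c(0.003, 0.004, 0.007, 0.003, 0.005, 0.004, 0.003, 0.060, 0.048),
    P_REPL    = c(1.65e-10, 4.92e-03, 4.21e-08, 3.17e-03, 9.54e-09, 1.70e-03,
                  3.715e-02, 1.056e-01, 6.55e-02),
    EAF_REPL  = c(58.5, 81.8, 92.6, 61.1, 12.3, 67.2, 53.2, 0.1, 0.2),
    N_REPL    = c(191580L, 191580L, 191580L, 191580L, 174831L, 191580L,
                  191580L, 174831L, 174831L),
    REPLICATED = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' LDSC intercepts of the published GIP discovery scans
#'
#' @return named vector of LD score regression intercepts for GIP1-GIP4.
#' @export
chronic_pain_gip_intercepts <- function() {
  c(GIP1 = 1.016, GIP2 = 1.001, GIP3 = 1.013, GIP4 = 1.021)
}

#' Published discovery-cohort case/control counts
#'
#' Case and control counts of the four chronic pain traits in the discovery
#' cohort (N = 265,000); prevalence is `cases / (cases + controls)`.
#'
#' @return a data frame with trait, cases and controls.
#' @export
chronic_pain_cohort_counts <- function() {
  data.frame(
    trait = c("back", "neck_shoulder", "hip", "knee"),
    cases = c(47507L, 43287L, 24300L, 46292L),
    controls = c(217493L, 221713L, 240700L, 218708L),
    stringsAsFactors = FALSE
  )
}
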