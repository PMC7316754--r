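# End-to-end discovery -> replication orchestration on simulated cohorts.

#' Configure a simulated discovery/replication study
#'
#' Bundles everything [run_pipeline()] needs: the trait architecture, the
#' LD-block layout, cohort sizes, the master seed (every stochastic stage
#' derives its own seed from it), LDSC settings, Monte Carlo draws and the
#' significance thresholds.
#'
#' @param arch a [trait_architecture()].
#' @param spec a [block_spec()].
#' @param n_discovery discovery cohort size.
#' @param n_replication vector of replication cohort sizes (one entry per
#'   cohort; their GIP GWAS are combined by [ivw_meta()]).
#' @param seed master integer seed.
#' @param causal optional sparse causal component passed to
#'   [simulate_traits()].
#' @param ld `"empirical"` (in-sample LD scores) or `"true"` (the analytic
#'   LD scores of the simulated LD model).
#' @param ldsc_blocks jackknife block count.
#' @param mc_draws Monte Carlo draws for loading CIs (0 to skip).
#' @param base_threshold per-phenotype genome-wide threshold (default 5e-8);
#'   the study-level threshold is `base_threshold / T`.
#' @param alpha family-wise rate for the replication gate.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return an object of class `"study_config"`.
#' @export
study_config <- function(arch, spec, n_discovery, n_replication, seed,
                         causal = NULL, ld = c("empirical", "true"),
                         ldsc_blocks = 200, mc_draws = 200,
                         base_threshold = 5e-8, alpha = 0.05,
                         out_dir = NULL) {
  stopifnot(inherits(arch, "trait_architecture"), inherits(spec, "block_spec"))
  if (missing(seed)) stop_("a master seed is required")
  structure(list(arch = arch, spec = spec,
                 n_discovery = as.integer(n_discovery),
                 n_replication = as.integer(n_replication),
                 seed = as.integer(seed), causal = causal,
                 ld = match.arg(ld), ldsc_blocks = ldsc_blocks,
                 mc_draws = mc_draws, base_threshold = base_threshold,
                 alpha = alpha, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Expects top-level keys `arch` (h2, rg, prevalence, env_cor, binary,
#' traits), `spec` (n_blocks, block_size, within_block_r, maf_range) and the
#' scalar fields of [study_config()].
#'
#' @param path YAML file path.
#' @return a `"study_config"`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  arch <- do.call(trait_architecture, y$arch)
  spec <- do.call(block_spec, y$spec)
  rest <- y[setdiff(names(y), c("arch", "spec"))]
  do.call(study_config, c(list(arch = arch, spec = spec), rest))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full discovery -> replication GIP study
#'
#' Simulates the discovery cohort, runs per-trait GWAS (traits standardized,
#' covariate-adjusted), estimates the genetic covariance matrix by LD Score
#' regression, fits the GIP decomposition (loadings are frozen here, before
#' any replication-cohort computation), runs per-GIP GWAS, corrects each GIP
#' scan with its own LDSC intercept, clumps loci at
#' `base_threshold / T`, simulates the replication cohorts, scores them with
#' the discovery loadings, meta-analyzes their GIP GWAS and applies the
#' replication gate.
#'
#' @param cfg a [study_config()].
#' @return (invisibly) a list with `cov_est`, `model`, `intercepts`,
#'   `trait_sumstats`, `gip_sumstats`, `loci`, `replication_meta`, `report`
#'   and `manifest`.  When `cfg$out_dir` is set, loadings, explained
#'   variance, the covariance matrices, GIP summary statistics, the loci
#'   table, the replication report and a machine-readable manifest are
#'   written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  seed <- cfg$seed
  T_ <- cfg$arch$n_traits
  M <- cfg$spec$n_blocks * cfg$spec$block_size

  message("stage: simulate discovery cohort")
  disc <- pipeline_stage("simulate_discovery", {
    co <- make_genotypes(cfg$n_discovery, cfg$spec, seed = seed + 1L)
    simulate_traits(co, cfg$arch, seed = seed + 2L, causal = cfg$causal)
  })

  message("stage: per-trait GWAS")
  trait_ss <- pipeline_stage("trait_gwas", {
    out <- lapply(cfg$arch$traits, function(tr)
      gwas_scan(disc, tr, covariates = disc$covariates, standardize_trait = TRUE))
    setNames(out, cfg$arch$traits)
  })

  message("stage: LD scores")
  ld <- pipeline_stage("ld_scores", {
    if (cfg$ld == "true")
      setNames(true_ld_scores(cfg$spec), disc$variant_meta$SNP)
    else ld_scores_empirical(disc)
  })

  message("stage: genetic covariance matrix (LDSC)")
  cov_est <- pipeline_stage("ldsc_cov_matrix",
    build_cov_matrix(trait_ss, ld, M = M, n_blocks = cfg$ldsc_blocks))

  message("stage: GIP decomposition")
  model <- pipeline_stage("gip_fit",
    suppressWarnings(gip(cov_est, mc_draws = cfg$mc_draws, seed = seed + 3L)))

  message("stage: discovery GIP GWAS")
  gip_ss <- pipeline_stage("gip_gwas",
    gip_gwas_individual(disc, model, covariates = disc$covariates))

  message("stage: per-GIP LDSC intercepts + GC correction")
  intercepts <- pipeline_stage("gip_intercepts", vapply(gip_ss, function(s)
    ldsc_univariate(s, ld, M = M, n_blocks = cfg$ldsc_blocks)$intercept,
    numeric(1)))
  # genomic control removes inflation only: an intercept below 1 (estimation
  # noise) is never allowed to amplify the test statistics
  gip_ss <- pipeline_stage("gc_correct", {
    out <- lapply(names(gip_ss), function(k)
      gc_correct(gip_ss[[k]], max(1, intercepts[[k]])))
    setNames(out, names(intercepts))
  })

  message("stage: locus clumping")
  threshold <- study_threshold(T_, base = cfg$base_threshold)
  loci <- pipeline_stage("clump", {
    per <- lapply(names(gip_ss), function(k) {
      l <- clump(gip_ss[[k]], threshold = threshold, p_col = "P_GC")
      if (nrow(l) > 0) l$PHENOTYPE <- k
      l
    })
    per <- per[vapply(per, nrow, integer(1)) > 0]
    if (length(per) > 0) do.call(rbind, per) else NULL
  })

  message("stage: replication cohorts")
  repl_meta <- pipeline_stage("replication", {
    per_cohort <- lapply(seq_along(cfg$n_replication), function(j) {
      co <- make_genotypes(cfg$n_replication[j], cfg$spec, seed = seed + 100L + j)
      co <- simulate_traits(co, cfg$arch, seed = seed + 200L + j, causal = cfg$causal)
      gip_gwas_individual(co, model, covariates = co$covariates)
    })
    out <- lapply(colnames(model$loadings), function(k)
      ivw_meta(lapply(per_cohort, `[[`, k)))
    setNames(out, colnames(model$loadings))
  })

  report <- if (!is.null(loci))
    pipeline_stage("replication_gate",
                   replication_gate(loci, repl_meta, alpha = cfg$alpha))
  else NULL

  manifest <- list(
    package = "gipkit",
    version = as.character(utils::packageVersion("gipkit")),
    seed = seed,
    stage_seeds = list(discovery_genotypes = seed + 1L,
                       discovery_traits = seed + 2L,
                       mc_ci = seed + 3L,
                       replication_genotypes = seed + 100L + seq_along(cfg$n_replication),
                       replication_traits = seed + 200L + seq_along(cfg$n_replication)),
    n_discovery = cfg$n_discovery, n_replication = cfg$n_replication,
    n_snps = M, n_traits = T_, ld = cfg$ld,
    ldsc_blocks = cfg$ldsc_blocks, mc_draws = cfg$mc_draws,
    discovery_threshold = threshold,
    replication_alpha = cfg$alpha,
    n_discovery_loci = if (is.null(loci)) 0L else nrow(loci),
    n_replicated = if (is.null(report)) 0L else sum(report$VERDICT == "replicated"),
    intercepts = as.list(intercepts)
  )

  res <- list(cov_est = cov_est, model = model, intercepts = intercepts,
              trait_sumstats = trait_ss, gip_sumstats = gip_ss,
              loci = loci, replication_meta = repl_meta, report = report,
              manifest = manifest)

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- res$model
  load_tab <- data.frame(TRAIT = model$traits, model$loadings, check.names = FALSE)
  if (!is.null(model$ci_lower)) {
    ci_lo <- model$ci_lower; ci_hi <- model$ci_upper
    colnames(ci_lo) <- paste0(colnames(model$loadings), "_CI2.5")
    colnames(ci_hi) <- paste0(colnames(model$loadings), "_CI97.5")
    load_tab <- cbind(load_tab, ci_lo, ci_hi)
  }
  utils::write.table(load_tab, file.path(out_dir, "loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(model$explained_total)) {
    ev <- data.frame(COMPONENT = colnames(model$loadings),
                     EIGENVALUE = model$eigenvalues,
                     EXPLAINED_TOTAL = model$explained_total)
    utils::write.table(ev, file.path(out_dir, "explained_variance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(model$explained_per_trait,
                     file.path(out_dir, "explained_per_trait.tsv"))
  }
  write_matrix_tsv(res$cov_est$C_G, file.path(out_dir, "genetic_covariance.tsv"))
  write_matrix_tsv(res$cov_est$intercepts, file.path(out_dir, "ldsc_intercepts.tsv"))
  J <- res$cov_est$J
  utils::write.table(data.frame(ENTRY = vech_labels(res$cov_est$traits), J,
                                check.names = FALSE),
                     file.path(out_dir, "jackknife_covariance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in names(res$gip_sumstats))
    write_sumstats(res$gip_sumstats[[k]],
                   file.path(out_dir, sprintf("sumstats_%s.tsv", k)))
  if (!is.null(res$loci))
    utils::write.table(res$loci, file.path(out_dir, "loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$report))
    utils::write.table(res$report, file.path(out_dir, "replication_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
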