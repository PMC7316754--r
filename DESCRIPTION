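Package: gipkit
Title: Genetically Independent Phenotypes from Multi-Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Decomposes a set of three or more genetically correlated traits
    into genetically independent phenotypes (GIPs): linear combinations of
    standardized traits whose weights are the eigenvectors of the genetic
    covariance matrix, so that the components are mutually uncorrelated at
    the genetic level and the first component captures the largest share of
    genetic variance. Provides a simplified LD Score regression estimator of
    SNP-based heritability and genetic covariance from GWAS summary
    statistics (with block-jackknife sampling covariance), covariate-adjusted
    single-SNP association scans, Monte Carlo confidence intervals for the
    transformation coefficients, GIP-level GWAS by both individual-level and
    summary-level routes, genomic-control correction via the regression
    intercept, fixed-effects inverse-variance meta-analysis, distance-based
    locus clumping, a discovery/replication decision procedure, and a
    synthetic-cohort simulator with LD-block genotypes and liability-threshold
    binary traits that supplies ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
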