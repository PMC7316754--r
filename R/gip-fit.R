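# The core model: decomposition of a genetic covariance matrix into
# genetically independent phenotypes (GIPs).
#
# The transformation coefficients (loadings) of GIP k are the k-th
# eigenvector of the genetic covariance matrix of the standardized traits;
# the eigenvalue is the genetic variance captured by that component.  GIPs
# are mutually uncorrelated at the genetic level and GIP1 captures the
# largest share of genetic variance.

# eigendecomposition with deterministic conventions:
#  - columns ordered by descending eigenvalue
#  - ties (|delta lambda| < 1e-12) broken by lexicographic order of the
#    absolute loadings
#  - sign fixed so each column sums > 0; if the sum is ~0, the largest
#    |loading| entry is made positive
gip_eigen <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  A <- e$vectors
  grp <- cumsum(c(TRUE, diff(lam) < -1e-12))
  for (gidx in unique(grp)) {
    idx <- which(grp == gidx)
    if (length(idx) > 1) {
      keys <- lapply(seq_len(nrow(A)), function(r) round(abs(A[r, idx]), 10))
      ord <- do.call(order, c(keys, list(decreasing = TRUE)))
      A[, idx] <- A[, idx][, ord]
    }
  }
  for (k in seq_len(ncol(A))) {
    s <- sum(A[, k])
    sgn <- if (abs(s) < 1e-12) sign(A[which.max(abs(A[, k])), k]) else sign(s)
    if (sgn < 0) A[, k] <- -A[, k]
  }
  list(values = lam, vectors = A)
}

#' Fit a genetically independent phenotype (GIP) model
#'
#' Decomposes a genetic covariance matrix of `T >= 3` standardized traits
#' into `T` genetically independent phenotypes by eigendecomposition.
#' Columns of the loading matrix are the orthogonal-transformation
#' coefficients; eigenvalues (sorted descending) are the genetic variances of
#' the components.  When the input carries a jackknife sampling covariance
#' (a [build_cov_matrix()] result), 95% Monte Carlo confidence intervals for
#' every loading are attached.
#'
#' Negative eigenvalues are permitted (estimation noise in `C_G`) and
#' flagged, never truncated.
#'
#' @param object a `"genetic_cov"` estimate, or a plain symmetric `T x T`
#'   matrix (then no confidence intervals are computed).
#' @param mc_draws number of Monte Carlo draws for loading confidence
#'   intervals (`>= 100`); set to 0 to skip.
#' @param seed seed for the Monte Carlo sampling.
#' @param allow_pairs permit `T = 2` (toy problems); the method is intended
#'   for three or more traits.
#' @return an object of class `"gip"` with components `loadings` (`T x T`,
#'   column k = coefficients of GIP k), `eigenvalues`, `explained_total`,
#'   `explained_per_trait`, `ci_lower`/`ci_upper` (when available), `C_G`,
#'   `J`, `traits`.
#' @seealso [explained_variance()], [monte_carlo_loading_ci()],
#'   [gip_scores()], [gip_h2()]
#' @examples
#' C <- matrix(0.03 * 0.7, 4, 4); diag(C) <- 0.03
#' fit <- gip(C)
#' coef(fit)            # near-equal GIP1 loadings
#' fit$eigenvalues      # 0.093, 0.009, 0.009, 0.009
#' @export
gip <- function(object, mc_draws = 1000, seed = NULL, allow_pairs = FALSE) {
  if (inherits(object, "genetic_cov")) {
    C <- object$C_G
    J <- object$J
    traits <- object$traits
  } else {
    C <- as.matrix(object)
    J <- NULL
    traits <- rownames(C) %||% paste0("trait", seq_len(nrow(C)))
  }
  T_ <- nrow(C)
  if (ncol(C) != T_) stop_("genetic covariance matrix must be square")
  if (max(abs(C - t(C))) > 1e-8) stop_("genetic covariance matrix is asymmetric beyond 1e-8")
  C <- (C + t(C)) / 2
  if (T_ < 3 && !allow_pairs)
    stop_("the GIP decomposition needs three or more traits (use allow_pairs = TRUE for toys)")

  e <- gip_eigen(C)
  A <- e$vectors
  lam <- e$values
  dimnames(A) <- list(traits, paste0("GIP", seq_len(T_)))
  names(lam) <- colnames(A)

  fit <- structure(list(loadings = A, eigenvalues = lam, C_G = C, J = J,
                        traits = traits, negative_eigenvalues = any(lam < 0),
                        ci_lower = NULL, ci_upper = NULL, mc_draws = 0L),
                   class = "gip")
  ev <- tryCatch(explained_variance(fit), error = function(e) NULL)
  fit$explained_total <- ev$explained_total
  fit$explained_per_trait <- ev$explained_per_trait

  if (!is.null(J) && mc_draws > 0) {
    ci <- monte_carlo_loading_ci(fit, J = J, n_draws = mc_draws, seed = seed)
    fit$ci_lower <- ci$lower
    fit$ci_upper <- ci$upper
    fit$mc_draws <- as.integer(mc_draws)
  }
  if (fit$negative_eigenvalues)
    warn_("negative eigenvalues present (noise in the genetic covariance estimate)")
  fit
}

#' Genetic variance explained by each GIP
#'
#' `explained_total[k] = lambda_k / sum(lambda)` is the share of total
#' genetic variance captured by GIP k;
#' `explained_per_trait[t, k] = loadings[t, k]^2 * lambda_k / C_G[t, t]` is
#' the share of trait t's genetic variance attributed to GIP k.  Each row of
#' `explained_per_trait` sums to 1 (an exact eigendecomposition identity)
#' whenever the trait's genetic variance is positive.
#'
#' @param model a fitted `"gip"` object.
#' @return list with `explained_total` (length T) and `explained_per_trait`
#'   (`T x T`).
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "gip"))
  lam <- model$eigenvalues
  tot <- sum(lam)
  if (tot <= 0) stop_("sum of eigenvalues is not positive: no genetic signal to apportion")
  A <- model$loadings
  per <- sweep(A^2, 2, lam, "*") / diag(model$C_G)
  list(explained_total = lam / tot, explained_per_trait = per)
}

#' Monte Carlo confidence intervals for GIP loadings
#'
#' Draws `vech(C_G*) ~ MVN(vech(C_G), J)` (half-vectorization, column-major
#' lower triangle), eigendecomposes each draw, matches the draw's columns to
#' the point-estimate columns greedily by maximal absolute inner product
#' (guarding against eigenvalue order switching under noise), flips signs so
#' the inner product is positive, and reports the 2.5% / 97.5% percentiles
#' of each loading across draws.
#'
#' @param model a fitted `"gip"` object.
#' @param J sampling covariance of `vech(C_G)`; if not positive
#'   semidefinite it is projected by clipping negative eigenvalues at zero
#'   (with a warning).
#' @param n_draws number of draws (`>= 100`).
#' @param seed optional seed.
#' @return list with `lower` and `upper` (`T x T` matrices).
#' @export
monte_carlo_loading_ci <- function(model, J = model$J, n_draws = 1000,
                                   seed = NULL) {
  stopifnot(inherits(model, "gip"))
  if (is.null(J)) stop_("no jackknife covariance available for the Monte Carlo sampling")
  if (n_draws < 100) stop_("n_draws must be at least 100")
  T_ <- length(model$traits)
  p <- T_ * (T_ + 1) / 2
  if (!isTRUE(all.equal(dim(J), c(p, p))))
    stop_("J must be %d x %d for %d traits", p, p, T_)
  ev <- eigen((J + t(J)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values), 1e-300))
    warn_("J is not positive semidefinite; projecting by eigenvalue clipping at 0")
  R <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  v0 <- vech(model$C_G)
  A0 <- model$loadings
  if (!is.null(seed)) set.seed(as.integer(seed))
  Z <- matrix(rnorm(n_draws * p), n_draws, p) %*% R

  draws <- array(NA_real_, c(n_draws, T_, T_))
  for (d in seq_len(n_draws)) {
    Cd <- unvech(v0 + Z[d, ], T_)
    ed <- eigen(Cd, symmetric = TRUE)
    S <- abs(crossprod(A0, ed$vectors))
    perm <- integer(T_)
    used <- logical(T_)
    for (step in seq_len(T_)) {
      S[, used] <- -Inf
      ij <- arrayInd(which.max(S), dim(S))
      perm[ij[1]] <- ij[2]
      used[ij[2]] <- TRUE
      S[ij[1], ] <- -Inf
    }
    Ad <- ed$vectors[, perm, drop = FALSE]
    flip <- colSums(A0 * Ad) < 0
    Ad[, flip] <- -Ad[, flip]
    draws[d, , ] <- Ad
  }
  lower <- apply(draws, c(2, 3), quantile, probs = 0.025, names = FALSE)
  upper <- apply(draws, c(2, 3), quantile, probs = 0.975, names = FALSE)
  dimnames(lower) <- dimnames(upper) <- dimnames(A0)
  list(lower = lower, upper = upper)
}
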