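# S3 methods for the fitted "gip" model.

#' @export
print.gip <- function(x, digits = 4, ...) {
  T_ <- length(x$traits)
  cat(sprintf("Genetically independent phenotypes: %d traits -> %d components\n\n",
              T_, T_))
  tab <- rbind(eigenvalue = x$eigenvalues,
               `explained (%)` = if (!is.null(x$explained_total))
                 100 * x$explained_total else rep(NA_real_, T_))
  print(round(tab, digits))
  cat("\nOrthogonal transformation coefficients (loadings):\n")
  print(round(x$loadings, digits))
  if (x$mc_draws > 0)
    cat(sprintf("\n95%% Monte Carlo CIs available (%d draws); see summary().\n",
                x$mc_draws))
  invisible(x)
}

#' @export
summary.gip <- function(object, ...) {
  out <- list(fit = object)
  if (!is.null(object$ci_lower)) {
    T_ <- length(object$traits)
    ci <- data.frame(
      trait = rep(object$traits, T_),
      component = rep(colnames(object$loadings), each = T_),
      loading = as.vector(object$loadings),
      lower = as.vector(object$ci_lower),
      upper = as.vector(object$ci_upper)
    )
    out$ci <- ci
  }
  class(out) <- "summary.gip"
  out
}

#' @export
print.summary.gip <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$ci)) {
    cat("\nLoadings with 95% Monte Carlo confidence intervals:\n")
    ci <- x$ci
    ci[c("loading", "lower", "upper")] <- round(ci[c("loading", "lower", "upper")], digits)
    print(ci, row.names = FALSE)
  }
  invisible(x)
}

#' Extract GIP loadings
#'
#' @param object a fitted `"gip"` model.
#' @param ... unused.
#' @return the `T x T` loading matrix (column k = coefficients of GIP k).
#' @export
coef.gip <- function(object, ...) object$loadings

#' Construct GIP scores for a cohort
#'
#' Applies the fitted orthogonal-transformation coefficients to a new trait
#' panel: each column is standardized within the scored cohort, then
#' `GIP_k = sum_t loadings[t, k] * y_std_t`.  Loadings are never refitted on
#' a replication cohort.
#'
#' @param object a fitted `"gip"` model.
#' @param newdata `n x T` matrix or data frame of traits; column names must
#'   match the model's traits (any order).
#' @param ... unused.
#' @return `n x T` matrix of GIP phenotype scores.
#' @export
predict.gip <- function(object, newdata, ...) gip_scores(newdata, object)

#' Plot GIP loadings
#'
#' Barplot of the orthogonal-transformation coefficients per component, with
#' 95% Monte Carlo confidence-interval whiskers when available.
#'
#' @param x a fitted `"gip"` model.
#' @param components which components to show (default all).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gip <- function(x, components = seq_along(x$traits), ...) {
  A <- x$loadings[, components, drop = FALSE]
  ylim <- range(0, A, x$ci_lower, x$ci_upper, na.rm = TRUE) * 1.1
  mid <- graphics::barplot(t(A), beside = TRUE, ylim = ylim,
                           legend.text = colnames(A),
                           ylab = "transformation coefficient",
                           names.arg = x$traits, ...)
  if (!is.null(x$ci_lower)) {
    lo <- t(x$ci_lower[, components, drop = FALSE])
    hi <- t(x$ci_upper[, components, drop = FALSE])
    graphics::arrows(mid, lo, mid, hi, angle = 90, code = 3, length = 0.03)
  }
  invisible(mid)
}
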