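# internal numerical helpers

#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom quantile
#'   pchisq qchisq pt cor cov cov2cor median sd uniroot integrate setNames
NULL

# symmetric PSD square root; negative eigenvalues (numerical noise) clipped at 0
psd_sqrt <- function(S, tol = 1e-12) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

is_psd <- function(S, tol = 1e-8) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1)
}

# half-vectorization (column-major lower triangle, diagonal included)
vech <- function(S) S[lower.tri(S, diag = TRUE)]

unvech <- function(v, n) {
  S <- matrix(0, n, n)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

# names of vech entries for a labeled matrix
vech_labels <- function(traits) {
  n <- length(traits)
  idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  paste(traits[idx[, 1]], traits[idx[, 2]], sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Legendre nodes/weights on (0, 1), cached
gauss_legendre_01 <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 64L) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    res <- list(x = (e$values + 1) / 2, w = 2 * e$vectors[1, ]^2 / 2)
    cache[[key]] <- res
    res
  }
})

# standard bivariate normal CDF P(X <= t1, Y <= t2; rho), vectorized over
# (t1, t2) pairs; quadrature after substituting the first margin's CDF
pbvnorm <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(pnorm(t1) * pnorm(t2))
  q <- gauss_legendre_01(64L)
  s <- sqrt(1 - rho^2)
  p1 <- pnorm(t1)
  Z <- qnorm(outer(q$x, p1))
  p1 * colSums(q$w * pnorm((rep(t2, each = length(q$x)) - rho * Z) / s))
}

# Pearson correlation of two indicators 1{X <= t1}, 1{Y <= t2} with latent
# correlation rho (vectorized over threshold pairs)
phi_corr <- function(rho, t1, t2) {
  p1 <- pnorm(t1)
  p2 <- pnorm(t2)
  (pbvnorm(t1, t2, rho) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# two-sided p-value from a z statistic, safe in the extreme tail
p_from_z <- function(z) 2 * pnorm(-abs(z))

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
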