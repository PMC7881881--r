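# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp, robust to -Inf rows.
row_logsumexp <- function(L) {
  m <- apply(L, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(L - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# x * log2(x) with the 0 * log 0 == 0 convention.
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

# Log density of a bivariate Gaussian, closed form (x: n x 2 matrix).
log_dmvnorm2 <- function(x, mean, cov) {
  d1 <- x[, 1L] - mean[1L]
  d2 <- x[, 2L] - mean[2L]
  dt <- cov[1L, 1L] * cov[2L, 2L] - cov[1L, 2L] * cov[2L, 1L]
  if (dt <= 0) stop("covariance matrix is not positive-definite")
  q <- (cov[2L, 2L] * d1^2 - 2 * cov[1L, 2L] * d1 * d2 + cov[1L, 1L] * d2^2) / dt
  -log(2 * pi) - 0.5 * log(dt) - 0.5 * q
}

# Draw n points from a bivariate Gaussian.
rmvnorm2 <- function(n, mean, cov) {
  ch <- chol(cov)
  z <- matrix(rnorm(2L * n), ncol = 2L)
  sweep(z %*% ch, 2L, mean, "+")
}

# Floor the eigenvalues of a 2x2 covariance at `floor` (px^2) to keep EM
# iterations away from singular components.
floor_cov <- function(cov, floor = 1) {
  cov <- (cov + t(cov)) / 2
  e <- eigen(cov, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% diag(vals) %*% t(e$vectors)
}

# Seed the RNG without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
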