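#' Fit a Gaussian mixture with BIC model selection
#'
#' Fits full-covariance Gaussian mixtures by EM for each candidate number of
#' components and returns the fit minimizing
#' `BIC = -2 logL + n_params * ln(n)`. Each Gaussian component models one
#' region of interest in the scene; the mixture as a whole models the pooled
#' gaze-point distribution. Backed by \pkg{mclust} (model "VVV").
#'
#' @param points n x 2 matrix of gaze points (px); needs `>= 10 * k_max` rows.
#' @param k_min,k_max candidate component-count range.
#' @param seed integer seed (EM initialization is deterministic given it).
#' @return A list with `gmm` (a [gaussian_mixture]), `M` (chosen count) and
#'   `bic` (named vector of BIC values per candidate, in the minimized form).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_gmm_bic <- function(points, k_min = 1L, k_max = 20L, seed = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, k_min >= 1L, k_max >= k_min)
  if (nrow(points) < 10L * k_max)
    stop("need at least 10 * k_max = ", 10L * k_max, " points")
  fit <- with_seed(seed, {
    mclust::Mclust(points, G = k_min:k_max, modelNames = "VVV",
                   verbose = FALSE)
  })
  if (is.null(fit)) stop("mixture fit failed for all candidate sizes")
  # mclust maximizes 2 logL - k log n; convert to the minimized form.
  bic <- -as.numeric(fit$BIC[, "VVV"])
  names(bic) <- rownames(fit$BIC)
  M <- fit$G
  covs <- fit$parameters$variance$sigma
  gmm <- gaussian_mixture(fit$parameters$pro, t(fit$parameters$mean),
                          array(covs, c(2L, 2L, M)))
  list(gmm = gmm, M = M, bic = bic, loglik = fit$loglik)
}

#' Re-estimate mixture weights with frozen component shapes
#'
#' EM over the mixing weights only: component means and covariances are
#' returned bit-identical to the input. This is the group-reweighting step —
#' regions of interest are identified once on pooled data, then each
#' subgroup's dwell profile over those fixed regions is expressed through
#' its own weight vector.
#'
#' @param gmm a `gaussian_mixture` fit on pooled data.
#' @param points n x 2 matrix of the subgroup's gaze points.
#' @param max_iter,tol EM stopping rule on the log-likelihood.
#' @return A `gaussian_mixture` with updated weights; attribute `loglik`
#'   holds the trace.
#' @export
reweight_mixture <- function(gmm, points, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(gmm, "gaussian_mixture"))
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("no points supplied")
  M <- n_components(gmm)
  # Weight-independent part of the component log densities.
  base <- gmm_component_logdens(gmm, points) -
    matrix(log(gmm$weights), nrow(points), M, byrow = TRUE)
  w <- gmm$weights
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    L <- base + matrix(log(pmax(w, 1e-300)), nrow(points), M, byrow = TRUE)
    norm <- row_logsumexp(L)
    ll <- sum(norm)
    ll_trace <- c(ll_trace, ll)
    r <- exp(L - norm)
    w <- colSums(r) / nrow(points)
    if (ll - ll_prev < tol && it > 1L) break
    ll_prev <- ll
  }
  out <- gmm
  out$weights <- w / sum(w)
  attr(out, "loglik") <- ll_trace
  out
}

#' Determinant of the weighted between-cluster covariance
#'
#' Spread statistic over mixture components:
#' `Sigma_b = sum_i pi_i (m_i - m_bar)(m_i - m_bar)^T` with
#' `m_bar = sum_i pi_i m_i`; returns `det(Sigma_b)` in px^4. Larger values
#' mean the regions of interest (weighted by dwell) are spread more widely
#' over the scene. In 2-D the determinant is 0 whenever the weighted means
#' are collinear (rank-deficient `Sigma_b`).
#'
#' @param weights component weights, summing to 1.
#' @param means matrix of component means, one row per component.
#' @return `det(Sigma_b) >= 0`. A single cluster yields 0 with a warning.
#' @export
between_cluster_cov_det <- function(weights, means) {
  means <- rbind(means)
  stopifnot(length(weights) == nrow(means))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (nrow(means) < 2L) {
    warning("single cluster: between-cluster covariance is identically 0")
    return(0)
  }
  mbar <- colSums(weights * means)
  d <- sweep(means, 2L, mbar)
  S <- crossprod(d * sqrt(weights))
  max(det(S), 0)
}
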