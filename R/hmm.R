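#' Stationary distribution of a row-stochastic transition matrix
#'
#' Solves `pi %*% A = pi` with `sum(pi) = 1`, i.e. the left eigenvector of
#' `A` for eigenvalue 1 (the null vector of `t(A) - I`). For a reducible
#' chain (an absorbing state, off-diagonal of a row equal to 0) the limit
#' depends on the start state; the point mass on the absorbing state is
#' returned with a warning.
#'
#' @param A square row-stochastic matrix.
#' @return Numeric stationary distribution, same length as `nrow(A)`.
#' @export
steady_state <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  stopifnot(ncol(A) == n)
  if (any(A < -1e-12) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("A must be row-stochastic")
  if (n == 2L) {
    a12 <- A[1L, 2L]; a21 <- A[2L, 1L]
    if (a12 + a21 == 0) {
      warning("reducible chain: both states absorbing; returning point mass on state 1")
      return(c(1, 0))
    }
    if (a12 == 0 || a21 == 0) {
      absorbing <- if (a12 == 0) 1L else 2L
      warning("reducible chain: returning point mass on absorbing state ", absorbing)
      pi_ <- numeric(2L); pi_[absorbing] <- 1
      return(pi_)
    }
    return(c(a21, a12) / (a12 + a21))
  }
  # General case: null vector of t(A) - I with the normalization row appended.
  M <- rbind(t(A) - diag(n), rep(1, n))
  pi_ <- qr.solve(M, c(rep(0, n), 1))
  pi_ <- pmax(pi_, 0)
  pi_ / sum(pi_)
}

#' Gaze transition entropy
#'
#' Stationary-weighted entropy of the transition rows of a Markov chain,
#' `H = -sum_i pi_i sum_j a_ij log2 a_ij`, with the `0 log 0 == 0`
#' convention. For a two-state chain H lies in `[0, 1]` bits: it attains its
#' maximum, 1 bit, when every transition probability is uniform (rapid
#' switching between the central and peripheral states) and its minimum,
#' 0 bits, when each row is a point mass (no transitions). Lower values
#' index more deliberative, focused scanning.
#'
#' @param A row-stochastic transition matrix.
#' @param pi_ stationary distribution; computed from `A` when omitted.
#' @return Entropy in bits.
#' @export
transition_entropy <- function(A, pi_ = NULL) {
  A <- as.matrix(A)
  if (is.null(pi_)) pi_ <- steady_state(A)
  if (length(pi_) != nrow(A)) stop("pi_ length must match nrow(A)")
  row_h <- -rowSums(xlog2x(A))
  sum(pi_ * row_h)
}

# ---- Baum-Welch core ------------------------------------------------------

# Per-state log emission densities for all observations: n x 2 matrix.
hmm_log_emission <- function(hmm, x) {
  cbind(gmm_logdens(hmm$emissions[[1L]], x),
        gmm_logdens(hmm$emissions[[2L]], x))
}

# Scaled-space forward-backward (per-step normalization; emission rows are
# max-shifted in log space first, so arbitrarily small densities are safe).
# Returns gamma (n x k), expected transition counts xi_sum (k x k), loglik.
forward_backward <- function(logA, logp, logB) {
  n <- nrow(logB); k <- ncol(logB)
  A <- exp(logA); p <- exp(logp)
  shift <- apply(logB, 1L, max)
  B <- exp(logB - shift)
  alpha <- matrix(0, n, k)
  cscale <- numeric(n)
  a <- p * B[1L, ]
  cscale[1L] <- sum(a)
  alpha[1L, ] <- a / cscale[1L]
  for (t in 2L:n) {
    a <- (alpha[t - 1L, ] %*% A) * B[t, ]
    cscale[t] <- sum(a)
    alpha[t, ] <- a / cscale[t]
  }
  ll <- sum(log(cscale)) + sum(shift)
  beta <- matrix(0, n, k)
  beta[n, ] <- 1
  for (t in (n - 1L):1L) {
    beta[t, ] <- A %*% (B[t + 1L, ] * beta[t + 1L, ]) / cscale[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, k, k)
  bb <- B[2L:n, , drop = FALSE] * beta[2L:n, , drop = FALSE] /
    cscale[2L:n]
  al <- alpha[1L:(n - 1L), , drop = FALSE]
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xi_sum[i, j] <- A[i, j] * sum(al[, i] * bb[, j])
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = ll)
}

# One EM pass; `update` selects which parameter blocks move. `seq` assigns
# each observation to an independent chain segment (the chain restarts at
# every segment boundary, so gaps in the data never fabricate transitions).
# Returns the updated model and the loglik of the *input* model.
baum_welch_step <- function(hmm, x, update, cov_floor = 1,
                            seq = rep(1L, nrow(x))) {
  logB_all <- hmm_log_emission(hmm, x)
  logA <- log(hmm$A); logp <- log(hmm$p)
  ids <- unique(seq)
  gamma <- matrix(0, nrow(x), 2L)
  xi_sum <- matrix(0, 2L, 2L)
  ll <- 0
  p1 <- numeric(2L)
  for (id in ids) {
    idx <- which(seq == id)
    if (length(idx) < 2L) next
    fb <- forward_backward(logA, logp, logB_all[idx, , drop = FALSE])
    gamma[idx, ] <- fb$gamma
    xi_sum <- xi_sum + fb$xi_sum
    ll <- ll + fb$loglik
    p1 <- p1 + fb$gamma[1L, ]
  }
  fb <- list(gamma = gamma, xi_sum = xi_sum, loglik = ll)
  new <- hmm
  if ("A" %in% update) {
    A <- fb$xi_sum
    rs <- rowSums(A)
    for (i in 1:2) {
      if (rs[i] > 0) A[i, ] <- A[i, ] / rs[i] else A[i, ] <- hmm$A[i, ]
    }
    new$A <- A
  }
  if ("p" %in% update) new$p <- p1 / sum(p1)
  if ("emissions" %in% update) {
    for (i in 1:2) {
      gmm <- hmm$emissions[[i]]
      Lc <- gmm_component_logdens(gmm, x)           # n x M
      r <- exp(Lc - row_logsumexp(Lc)) * fb$gamma[, i]
      Nm <- colSums(r)
      if (any(!is.finite(Nm))) stop("non-finite responsibility in state ", i)
      w <- Nm / sum(Nm)
      means <- gmm$means
      covs <- gmm$covs
      for (m in seq_len(n_components(gmm))) {
        if (Nm[m] < 1e-8) next   # starved component: keep previous parameters
        mu <- colSums(r[, m] * x) / Nm[m]
        d <- sweep(x, 2L, mu)
        S <- crossprod(d * sqrt(r[, m])) / Nm[m]
        means[m, ] <- mu
        covs[, , m] <- floor_cov(S, cov_floor)
      }
      new$emissions[[i]] <- gaussian_mixture(w, means, covs)
    }
  }
  list(hmm = new, loglik = fb$loglik, gamma = fb$gamma)
}

# Observation matrix for HMM fitting, with a "seq" attribute marking
# independent chain segments: consecutive fixations that are not
# time-adjacent (gap > max_gap_s between one fixation's end and the next
# one's start) belong to different segments, since unobserved fixations may
# lie in between.
as_obs_matrix <- function(x, granularity = c("fixation", "sample"),
                          max_gap_s = 0.15) {
  granularity <- match.arg(granularity)
  if (inherits(x, "gaze_trajectory")) {
    if (granularity == "fixation") {
      fs <- segment_fixations(x)
      fixation_obs(fs, max_gap_s)
    } else {
      as.matrix(x[x$valid, c("x_px", "y_px")])
    }
  } else {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2L)
    x
  }
}

#' Fixation-centroid observations for HMM fitting
#'
#' Extracts the centroid matrix from a [fixation_sequence], with a `seq`
#' attribute splitting the sequence wherever consecutive fixations are not
#' time-adjacent (gap above `max_gap_s`): unobserved fixations may hide in
#' such gaps, and treating the flanking fixations as consecutive would
#' fabricate state transitions. Baum-Welch restarts its chain at every
#' segment boundary.
#'
#' @param fs a `fixation_sequence`.
#' @param max_gap_s largest end-to-start gap (s) still treated as
#'   consecutive.
#' @return n x 2 matrix of centroids with attribute `seq`.
#' @export
fixation_obs <- function(fs, max_gap_s = 0.15) {
  stopifnot(inherits(fs, "fixation_sequence"))
  fx <- fs$fixations
  obs <- as.matrix(fx[, c("x_px", "y_px")])
  n <- nrow(fx)
  if (n > 1L) {
    gap <- fx$start_s[-1L] - fx$end_s[-n]
    attr(obs, "seq") <- cumsum(c(1L, as.integer(gap > max_gap_s)))
  } else {
    attr(obs, "seq") <- rep(1L, n)
  }
  obs
}

obs_seq <- function(obs) {
  attr(obs, "seq") %||% rep(1L, nrow(obs))
}

#' Fit the two-state gaze HMM by Baum-Welch
#'
#' Expectation-maximization over all parameter blocks (transition matrix,
#' initial probabilities, GMM emission weights/means/covariances), run to a
#' log-likelihood tolerance of `tol` or `max_iter` iterations. Observations
#' are fixation centroids by default (one observation per fixation, obtained
#' through [segment_fixations()]); per-sample fitting is available via
#' `granularity = "sample"`.
#'
#' @param x a `gaze_trajectory`, or an n x 2 matrix of observations in pixels.
#' @param init a `gaze_hmm` giving the starting point (see [init_gaze_hmm()]).
#' @param seed optional integer; the fit itself is deterministic given
#'   `init`, the seed only matters if `init` is created inside.
#' @param granularity `"fixation"` (default) or `"sample"`.
#' @param max_iter,tol EM stopping rule.
#' @param cov_floor eigenvalue floor for emission covariances, px^2.
#' @param update parameter blocks to re-estimate.
#' @return A fitted `gaze_hmm` with attributes `loglik` (trace, one value per
#'   iteration) and `n_obs`.
#' @export
train_hmm <- function(x, init, seed = NULL, granularity = "fixation",
                      max_iter = 500L, tol = 1e-5, cov_floor = 1,
                      update = c("A", "p", "emissions")) {
  obs <- as_obs_matrix(x, granularity)
  if (nrow(obs) < 10L) stop("need at least 10 observations to fit the HMM")
  sq <- obs_seq(obs)
  hmm <- init
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    step <- baum_welch_step(hmm, obs, update, cov_floor, seq = sq)
    if (!is.finite(step$loglik))
      stop("non-finite log-likelihood at iteration ", it)
    ll_trace <- c(ll_trace, step$loglik)
    if (step$loglik - ll_prev < tol && it > 1L) {
      hmm <- step$hmm
      break
    }
    ll_prev <- step$loglik
    hmm <- step$hmm
  }
  attr(hmm, "loglik") <- ll_trace
  attr(hmm, "n_obs") <- nrow(obs)
  hmm
}

#' Re-estimate transition probabilities on a data segment
#'
#' Constrained Baum-Welch over the transition matrix only: emission GMMs and
#' initial state probabilities are held fixed (bit-identical on return).
#' This is the per-window step of the analysis, re-fitting `A` inside each
#' three-minute viewing window while the subject-independent emission model
#' stays frozen. If a state is effectively unvisited in the segment
#' (expected occupancy below 1 observation), its row cannot be identified;
#' that row falls back to the input model's row with a warning.
#'
#' @param hmm fitted subject-independent `gaze_hmm`.
#' @param segment a `gaze_trajectory` (>= 30 s of valid data recommended) or
#'   an n x 2 observation matrix.
#' @inheritParams train_hmm
#' @return 2 x 2 row-stochastic transition matrix.
#' @export
reestimate_transitions <- function(hmm, segment, granularity = "fixation",
                                   max_iter = 500L, tol = 1e-5) {
  obs <- as_obs_matrix(segment, granularity)
  if (nrow(obs) < 2L) stop("segment too short to estimate transitions")
  sq <- obs_seq(obs)
  cur <- hmm
  ll_prev <- -Inf
  gamma <- NULL
  for (it in seq_len(max_iter)) {
    step <- baum_welch_step(cur, obs, update = "A", seq = sq)
    gamma <- step$gamma
    if (step$loglik - ll_prev < tol && it > 1L) {
      cur <- step$hmm
      break
    }
    ll_prev <- step$loglik
    cur <- step$hmm
  }
  occupancy <- colSums(gamma)
  A <- cur$A
  for (i in 1:2) {
    if (occupancy[i] < 1) {
      warning("state ", i, " effectively unvisited in segment (occupancy ",
              signif(occupancy[i], 3), "); falling back to the pooled row")
      A[i, ] <- hmm$A[i, ]
    }
  }
  A
}

#' Random initialization for the gaze HMM
#'
#' Stands in for manual initialization from inspected heatmaps: component
#' means are seeded by k-means on the observations, split into a central
#' group (components nearest the image center) and a peripheral group;
#' mixture weights, transition probabilities and initial probabilities are
#' drawn randomly, as in the reference fitting recipe.
#'
#' @param x observation matrix or `gaze_trajectory`.
#' @param n_central,n_peripheral number of mixture components per state.
#' @param dims image dimensions `c(width, height)` in pixels.
#' @param seed integer seed governing the random parameter blocks.
#' @return A `gaze_hmm` suitable as `init` for [train_hmm()].
#' @export
init_gaze_hmm <- function(x, n_central = 4L, n_peripheral = 9L,
                          dims = c(960L, 720L), seed = NULL) {
  obs <- as_obs_matrix(x, "sample")
  k <- n_central + n_peripheral
  with_seed(seed, {
    km <- kmeans(obs, centers = min(k, nrow(unique(obs))), nstart = 5L,
                 iter.max = 50L)
    centers <- km$centers
    ctr <- dims / 2
    d2 <- rowSums(sweep(centers, 2L, ctr)^2)
    ord <- order(d2)
    central_idx <- ord[seq_len(min(n_central, nrow(centers)))]
    periph_idx <- setdiff(seq_len(nrow(centers)), central_idx)
    if (length(periph_idx) == 0L) periph_idx <- central_idx
    mk_gmm <- function(idx) {
      M <- length(idx)
      w <- runif(M) + 0.5
      covs <- array(0, c(2L, 2L, M))
      spread <- stats::var(obs)
      for (m in seq_len(M)) covs[, , m] <- floor_cov(spread / M, 25)
      gaussian_mixture(w / sum(w), centers[idx, , drop = FALSE], covs)
    }
    A <- matrix(runif(4, 0.2, 0.8), 2L)
    A <- A / rowSums(A)
    p <- runif(2L); p <- p / sum(p)
    gaze_hmm(A, p, list(mk_gmm(central_idx), mk_gmm(periph_idx)))
  })
}

#' Generate a gaze trajectory from a fitted HMM
#'
#' Ancestral sampling: draw the state sequence from the chain, then one
#' emission per step from the active state's GMM. Used to compare
#' model-generated heatmaps against measured ones (KL divergence check).
#'
#' @param hmm a `gaze_hmm`.
#' @param n number of observations to draw.
#' @param seed integer seed.
#' @param dims image dimensions; draws are clamped to the frame.
#' @param rate nominal sample rate (Hz) used to timestamp the draws.
#' @return A list with `traj` (a `gaze_trajectory`) and `states` (integer
#'   vector of generating states).
#' @export
generate_from_hmm <- function(hmm, n, seed = NULL, dims = c(960L, 720L),
                              rate = 60) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    states <- integer(n)
    states[1L] <- sample.int(2L, 1L, prob = hmm$p)
    if (n > 1L) for (t in 2L:n) {
      states[t] <- sample.int(2L, 1L, prob = hmm$A[states[t - 1L], ])
    }
    xy <- matrix(0, n, 2L)
    for (s in 1:2) {
      idx <- states == s
      if (any(idx)) xy[idx, ] <- gmm_sample(hmm$emissions[[s]], sum(idx))
    }
    xy[, 1L] <- pmin(pmax(xy[, 1L], 0), dims[1L] - 1e-6)
    xy[, 2L] <- pmin(pmax(xy[, 2L], 0), dims[2L] - 1e-6)
    traj <- gaze_trajectory(seq_len(n) / rate, xy[, 1L], xy[, 2L],
                            image_dims = dims)
    list(traj = traj, states = states)
  })
}
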