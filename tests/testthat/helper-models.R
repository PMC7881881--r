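# Shared fixtures, built in code.

# Two-state HMM with well-separated single-Gaussian emissions: cheap and
# unambiguous for recovery tests.
two_state_hmm <- function(A = matrix(c(0.9, 0.3, 0.1, 0.7), 2L),
                          p = NULL) {
  g1 <- gaussian_mixture(1, matrix(c(250, 360), 1L),
                         array(diag(c(900, 900)), c(2L, 2L, 1L)))
  g2 <- gaussian_mixture(1, matrix(c(710, 360), 1L),
                         array(diag(c(900, 900)), c(2L, 2L, 1L)))
  if (is.null(p)) p <- suppressWarnings(steady_state(A))
  gaze_hmm(A, p, list(g1, g2))
}

# Stationary trajectory with tiny jitter around a point.
stationary_traj <- function(n = 600L, center = c(480, 360), jitter = 0.5,
                            rate = 60, seed = 1L) {
  set.seed(seed)
  gaze_trajectory((seq_len(n) - 1L) / rate,
                  center[1L] + rnorm(n, 0, jitter),
                  center[2L] + rnorm(n, 0, jitter))
}

# Random row-stochastic 2x2 matrix (rows ~ Dirichlet(1,1)).
random_stochastic_2x2 <- function() {
  r1 <- runif(1); r2 <- runif(1)
  matrix(c(r1, r2, 1 - r1, 1 - r2), 2L)
}
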