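test_that("steady state solves pi A = pi and handles reducible chains", {
  expect_equal(steady_state(matrix(0.5, 2L, 2L)), c(0.5, 0.5))
  A <- matrix(c(0.9, 0.3, 0.1, 0.7), 2L)
  pi_ <- steady_state(A)
  expect_equal(pi_, c(0.75, 0.25), tolerance = 1e-12)
  # cross-check by power iteration
  v <- c(1, 0)
  for (i in 1:200) v <- as.numeric(v %*% A)
  expect_equal(pi_, v, tolerance = 1e-10)
  expect_warning(pi_abs <- steady_state(diag(2)), "reducible")
  expect_equal(sum(pi_abs), 1)
  expect_error(steady_state(matrix(c(0.5, 0.2, 0.6, 0.8), 2L)),
               "row-stochastic")
})

test_that("transition entropy matches its stated extremes and closed form", {
  expect_identical(transition_entropy(matrix(0.5, 2L, 2L)), 1)
  expect_identical(transition_entropy(diag(2), pi_ = c(1, 0)), 0)
  A <- matrix(c(0.9, 0.3, 0.1, 0.7), 2L)
  h2 <- function(q) -q * log2(q) - (1 - q) * log2(1 - q)
  expect_equal(transition_entropy(A, c(0.75, 0.25)),
               0.75 * h2(0.9) + 0.25 * h2(0.7), tolerance = 1e-15)
  expect_equal(transition_entropy(A, c(0.75, 0.25)), 0.572, tolerance = 5e-4)
  expect_error(transition_entropy(A, c(1, 0, 0)), "length")
})

test_that("heatmap KL divergence matches direct evaluation and is nonnegative", {
  p <- matrix(c(0.5, 0.5), 1L)
  q <- matrix(c(0.75, 0.25), 1L)
  expect_identical(heatmap_kl(p, p), 0)
  expect_equal(heatmap_kl(p, q),
               0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25),
               tolerance = 1e-15)
  expect_equal(heatmap_kl(p, q), 0.2075, tolerance = 1e-3)
  set.seed(4)
  for (i in 1:20) {
    a <- runif(16); a <- a / sum(a)
    b <- runif(16) + 0.01; b <- b / sum(b)
    expect_gte(heatmap_kl(matrix(a, 4L), matrix(b, 4L)), 0)
  }
  expect_error(heatmap_kl(matrix(1, 1L), matrix(c(0.5, 0.5), 2L)), "dimensions")
  expect_warning(
    kl <- heatmap_kl(matrix(c(0.5, 0.5), 1L), matrix(c(1, 0), 1L)),
    "support")
  expect_identical(kl, Inf)
})

test_that("between-cluster covariance determinant matches hand computation", {
  expect_equal(between_cluster_cov_det(c(0.3, 0.7), rbind(c(5, 5), c(5, 5))), 0)
  # two clusters: rank-1 spread, zero determinant in 2-D
  expect_equal(between_cluster_cov_det(c(0.5, 0.5), rbind(c(0, 0), c(10, 4))),
               0, tolerance = 1e-9)
  expect_equal(between_cluster_cov_det(rep(1 / 3, 3),
                                       rbind(c(0, 0), c(1, 0), c(0, 1))),
               1 / 27, tolerance = 1e-12)
  expect_warning(z <- between_cluster_cov_det(1, rbind(c(2, 3))), "single")
  expect_identical(z, 0)
  expect_error(between_cluster_cov_det(c(0.5, 0.7), rbind(c(0, 0), c(1, 1))),
               "sum to 1")
})

test_that("BIC selects the generating number of mixture components", {
  set.seed(10)
  pts3 <- rbind(cbind(rnorm(300, 150, 5), rnorm(300, 150, 5)),
                cbind(rnorm(300, 500, 5), rnorm(300, 360, 5)),
                cbind(rnorm(300, 820, 5), rnorm(300, 600, 5)))
  fit3 <- fit_gmm_bic(pts3, 1L, 6L, seed = 1)
  expect_equal(fit3$M, 3L)
  expect_equal(which.min(fit3$bic), 3L, ignore_attr = TRUE)
  pts1 <- cbind(rnorm(400, 480, 40), rnorm(400, 360, 40))
  fit1 <- fit_gmm_bic(pts1, 1L, 4L, seed = 1)
  expect_equal(fit1$M, 1L)
  # determinism
  fit3b <- fit_gmm_bic(pts3, 1L, 6L, seed = 1)
  expect_identical(fit3$gmm, fit3b$gmm)
  expect_error(fit_gmm_bic(pts1[1:30, ], 1L, 6L), "at least")
})

test_that("reweighting recovers subgroup weights with frozen shapes", {
  g <- gaussian_mixture(c(0.25, 0.75),
                        rbind(c(200, 200), c(700, 500)),
                        array(rep(diag(c(400, 400)), 2L), c(2L, 2L, 2L)))
  set.seed(11)
  # points from component 1 only
  p1 <- matrix(rnorm(400, 200, 20), ncol = 2L)
  rw1 <- reweight_mixture(g, p1)
  expect_gt(rw1$weights[1L], 1 - 1e-3)
  # points from the mixture itself, generating weights (0.3, 0.7)
  n <- 4000L
  comp <- rbinom(n, 1L, 0.7) + 1L
  mus <- g$means[comp, ]
  pts <- mus + matrix(rnorm(2L * n, 0, 20), ncol = 2L)
  rw <- reweight_mixture(g, pts)
  expect_lt(max(abs(rw$weights - c(0.3, 0.7))), 0.02)
  # frozen-parameter contract: means and covariances bit-identical
  expect_identical(rw$means, g$means)
  expect_identical(rw$covs, g$covs)
  expect_error(reweight_mixture(g, matrix(numeric(0), ncol = 2L)), "no points")
})

test_that("Baum-Welch recovers transition structure from generated data", {
  A <- matrix(c(0.9, 0.3, 0.1, 0.7), 2L)
  hmm <- two_state_hmm(A = A)
  out <- generate_from_hmm(hmm, n = 10000L, seed = 21)
  obs <- as.matrix(out$traj[, c("x_px", "y_px")])
  init <- init_gaze_hmm(obs, 1L, 1L, seed = 22)
  fit <- train_hmm(obs, init)
  # states may come out swapped; align by emission mean x
  ord <- order(c(fit$emissions[[1L]]$means[1L, 1L],
                 fit$emissions[[2L]]$means[1L, 1L]))
  Ahat <- fit$A[ord, ord]
  expect_lt(max(abs(Ahat - A)), 0.05)
  # monotone non-decreasing log-likelihood
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-6))
  # determinism: same data, same init
  fit2 <- train_hmm(obs, init)
  expect_identical(fit$A, fit2$A)
})

test_that("training from the generating parameters converges immediately", {
  A <- matrix(c(0.9, 0.3, 0.1, 0.7), 2L)
  hmm <- two_state_hmm(A = A)
  out <- generate_from_hmm(hmm, n = 2000L, seed = 23)
  obs <- as.matrix(out$traj[, c("x_px", "y_px")])
  fit <- train_hmm(obs, hmm, update = c("A", "p"))
  ll <- attr(fit, "loglik")
  expect_lt(length(ll), 25L)
  expect_lt(max(abs(fit$A - A)), 0.05)
})

test_that("transition re-estimation is constrained and recovers the window chain", {
  A <- matrix(c(0.9, 0.3, 0.1, 0.7), 2L)
  hmm <- two_state_hmm(A = A)
  # absorbing segment: all observations from state 1
  abs_hmm <- two_state_hmm(A = diag(2), p = c(1, 0))
  seg <- generate_from_hmm(abs_hmm, n = 600L, seed = 31)
  obs1 <- as.matrix(seg$traj[, c("x_px", "y_px")])
  suppressWarnings(A1 <- reestimate_transitions(hmm, obs1))
  expect_gt(A1[1L, 1L], 0.99)
  expect_equal(rowSums(A1), c(1, 1), tolerance = 1e-9)
  # 3-minute-scale windows: average re-estimate over 5 windows
  As <- lapply(1:5, function(s) {
    w <- generate_from_hmm(hmm, n = 514L, seed = 40 + s)
    reestimate_transitions(hmm, as.matrix(w$traj[, c("x_px", "y_px")]))
  })
  Abar <- Reduce("+", As) / length(As)
  expect_lt(max(abs(Abar - A)), 0.05)
  # frozen contract: emissions and p of the input model untouched
  before <- hmm
  suppressWarnings(reestimate_transitions(hmm, obs1))
  expect_identical(hmm$emissions, before$emissions)
  expect_identical(hmm$p, before$p)
})

test_that("generated trajectories respect seeds and the frame", {
  hmm <- two_state_hmm()
  a <- generate_from_hmm(hmm, 500L, seed = 51)
  b <- generate_from_hmm(hmm, 500L, seed = 51)
  expect_identical(a, b)
  expect_true(all(a$traj$x_px >= 0 & a$traj$x_px < 960))
})
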