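#' Construct a gaze trajectory
#'
#' A gaze trajectory holds timestamped 2-D gaze samples in scene-image pixel
#' coordinates (origin top-left, x rightward, y downward, 0-based pixel
#' indices) together with a per-sample validity flag. Invalid samples mark
#' blinks or off-scene gaze and are ignored by every downstream metric.
#'
#' @param t_s numeric vector of sample times in seconds, strictly increasing.
#' @param x_px,y_px numeric vectors of gaze coordinates in pixels.
#' @param valid logical vector; `FALSE` marks dropout samples.
#' @param image_dims integer vector `c(width, height)` of the scene image.
#' @return An object of class `gaze_trajectory`: a data frame with columns
#'   `t_s`, `x_px`, `y_px`, `valid` and an `image_dims` attribute.
#' @export
gaze_trajectory <- function(t_s, x_px, y_px, valid = NULL,
                            image_dims = c(960L, 720L)) {
  n <- length(t_s)
  if (is.null(valid)) valid <- rep(TRUE, n)
  stopifnot(length(x_px) == n, length(y_px) == n, length(valid) == n,
            length(image_dims) == 2L, all(image_dims > 0))
  if (n > 1L && any(diff(t_s) <= 0)) {
    bad <- which(diff(t_s) <= 0)[1L] + 1L
    stop("timestamps must be strictly increasing (violated at row ", bad, ")")
  }
  v <- valid & is.finite(x_px) & is.finite(y_px)
  inside <- x_px >= 0 & x_px < image_dims[1L] & y_px >= 0 & y_px < image_dims[2L]
  if (any(v & !inside)) {
    bad <- which(v & !inside)[1L]
    stop("valid sample outside the image frame at row ", bad)
  }
  out <- data.frame(t_s = as.numeric(t_s), x_px = as.numeric(x_px),
                    y_px = as.numeric(y_px), valid = as.logical(valid))
  attr(out, "image_dims") <- as.integer(image_dims)
  class(out) <- c("gaze_trajectory", "data.frame")
  out
}

image_dims <- function(traj) attr(traj, "image_dims")

#' @export
print.gaze_trajectory <- function(x, ...) {
  dims <- image_dims(x)
  cat(sprintf("<gaze_trajectory> %d samples over %.1f s, %d x %d px, %.1f%% valid\n",
              nrow(x), diff(range(x$t_s)), dims[1L], dims[2L],
              100 * mean(x$valid)))
  invisible(x)
}

#' Construct a raw physiological record
#'
#' A uniformly sampled single-channel recording: ECG in millivolts, GSR in
#' microsiemens, or BVP in arbitrary units. BVP is carried through the
#' pipeline but no metric is derived from it.
#'
#' @param values numeric sample vector.
#' @param rate sampling rate in Hz.
#' @param channel one of `"ECG"`, `"GSR"`, `"BVP"`.
#' @return An object of class `physio_record`.
#' @export
physio_record <- function(values, rate, channel = c("ECG", "GSR", "BVP")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(values), length(rate) == 1L, rate > 0)
  if (!all(is.finite(values))) stop("physio record contains non-finite values")
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 channel = channel),
            class = "physio_record")
}

#' @export
print.physio_record <- function(x, ...) {
  cat(sprintf("<physio_record> %s, %d samples at %g Hz (%.1f s)\n",
              x$channel, length(x$values), x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' Construct a bivariate Gaussian mixture
#'
#' @param weights mixing weights, nonnegative, summing to 1.
#' @param means numeric matrix, one row per component, columns x/y in pixels.
#' @param covs 2 x 2 x M array of component covariance matrices (px^2).
#' @return An object of class `gaussian_mixture`.
#' @export
gaussian_mixture <- function(weights, means, covs) {
  means <- rbind(means)
  M <- length(weights)
  stopifnot(nrow(means) == M, ncol(means) == 2L)
  if (M == 1L && length(dim(covs)) == 2L) covs <- array(covs, c(2L, 2L, 1L))
  stopifnot(identical(dim(covs)[1:2], c(2L, 2L)), dim(covs)[3L] == M)
  if (any(weights < -1e-12)) stop("mixture weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  for (m in seq_len(M)) {
    cm <- covs[, , m]
    if (max(abs(cm - t(cm))) > 1e-8 || any(eigen(cm, symmetric = TRUE,
                                                 only.values = TRUE)$values <= 0))
      stop("component ", m, ": covariance must be symmetric positive-definite")
  }
  structure(list(weights = as.numeric(weights), means = unname(means),
                 covs = unname(covs)),
            class = "gaussian_mixture")
}

n_components <- function(gmm) length(gmm$weights)

# n x M matrix of log(c_m) + log N(x; m_m, Sigma_m).
gmm_component_logdens <- function(gmm, x) {
  x <- rbind(x)
  M <- n_components(gmm)
  L <- matrix(0, nrow(x), M)
  for (m in seq_len(M)) {
    L[, m] <- log(gmm$weights[m]) + log_dmvnorm2(x, gmm$means[m, ], gmm$covs[, , m])
  }
  L
}

# Log mixture density per point.
gmm_logdens <- function(gmm, x) row_logsumexp(gmm_component_logdens(gmm, x))

# Ancestral draw of n points.
gmm_sample <- function(gmm, n) {
  comp <- sample.int(n_components(gmm), n, replace = TRUE, prob = gmm$weights)
  out <- matrix(0, n, 2L)
  for (m in unique(comp)) {
    idx <- comp == m
    out[idx, ] <- rmvnorm2(sum(idx), gmm$means[m, ], gmm$covs[, , m])
  }
  out
}

#' Construct a two-state gaze HMM
#'
#' The scanpath model: a two-state Markov chain (state 1 = central, state 2 =
#' peripheral) whose emission density in each state is a Gaussian mixture over
#' scene-image pixel coordinates.
#'
#' @param A 2 x 2 row-stochastic transition matrix, `A[i, j] = p(s_t = j | s_{t-1} = i)`.
#' @param p initial state probabilities (length 2, sums to 1).
#' @param emissions list of two `gaussian_mixture` objects (central, peripheral).
#' @return An object of class `gaze_hmm`.
#' @export
gaze_hmm <- function(A, p, emissions) {
  A <- as.matrix(A)
  stopifnot(identical(dim(A), c(2L, 2L)), length(p) == 2L,
            length(emissions) == 2L)
  if (any(A < -1e-12) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("transition matrix rows must be stochastic")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
    stop("initial probabilities must sum to 1")
  lapply(emissions, function(e) stopifnot(inherits(e, "gaussian_mixture")))
  structure(list(A = unname(A), p = as.numeric(p), emissions = emissions),
            class = "gaze_hmm")
}

#' @export
print.gaze_hmm <- function(x, ...) {
  cat("<gaze_hmm> 2 states (central, peripheral)\n")
  cat(sprintf("  mixtures: %d central, %d peripheral\n",
              n_components(x$emissions[[1L]]), n_components(x$emissions[[2L]])))
  cat("  A =\n")
  print(round(x$A, 4))
  invisible(x)
}
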