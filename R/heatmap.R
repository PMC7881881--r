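#' Gaze heatmap by Gaussian kernel smoothing
#'
#' Every valid gaze sample deposits an isotropic Gaussian kernel of standard
#' deviation `sigma` (default 10 px) centered at the sample; the accumulated
#' mass over the pixel grid is normalized to sum to 1. Kernels are truncated
#' at +/- 4 sigma. Samples are snapped to their nearest pixel before
#' accumulation (snapping error <= 0.5 px against sigma = 10 px), which lets
#' the accumulation run as two banded matrix products over the count grid.
#'
#' @param traj a `gaze_trajectory`; invalid samples are ignored.
#' @param sigma kernel standard deviation in pixels.
#' @return An object of class `gaze_heatmap`: a list with `grid` (height x
#'   width matrix of probability mass, rows indexed by y) and `sigma`.
#' @export
compute_heatmap <- function(traj, sigma = 10) {
  stopifnot(inherits(traj, "gaze_trajectory"), sigma > 0)
  dims <- image_dims(traj)
  w <- dims[1L]; h <- dims[2L]
  v <- traj$valid
  if (!any(v)) stop("no valid samples: cannot compute a heatmap")
  xi <- pmin(pmax(round(traj$x_px[v]), 0), w - 1L) + 1L
  yi <- pmin(pmax(round(traj$y_px[v]), 0), h - 1L) + 1L
  counts <- matrix(0, h, w)
  idx <- (xi - 1L) * h + yi
  tab <- tabulate(idx, nbins = h * w)
  counts[] <- tab
  K <- function(n) {
    pos <- seq_len(n) - 1L
    D <- outer(pos, pos, "-")
    kern <- exp(-D^2 / (2 * sigma^2))
    kern[abs(D) > 4 * sigma] <- 0
    kern
  }
  grid <- K(h) %*% counts %*% K(w)
  grid <- grid / sum(grid)
  structure(list(grid = grid, sigma = sigma), class = "gaze_heatmap")
}

#' @export
print.gaze_heatmap <- function(x, ...) {
  cat(sprintf("<gaze_heatmap> %d x %d px, sigma = %g px, entropy = %.2f bits\n",
              ncol(x$grid), nrow(x$grid), x$sigma, spatial_entropy(x)))
  invisible(x)
}

as_heatmap_grid <- function(hm) {
  grid <- if (inherits(hm, "gaze_heatmap")) hm$grid else as.matrix(hm)
  if (any(grid < 0)) stop("heatmap grid has negative mass")
  if (abs(sum(grid) - 1) > 1e-9) stop("heatmap grid is not normalized")
  grid
}

#' Spatial entropy of a gaze heatmap
#'
#' Shannon entropy in base 2 over the pixel grid, `-sum_x p(x) log2 p(x)`
#' with `0 log 0 == 0`. Bounded by `[0, log2(width * height)]`; larger values
#' mean more spatially distributed viewing.
#'
#' @param hm a `gaze_heatmap`, or a nonnegative matrix summing to 1.
#' @return Entropy in bits.
#' @export
spatial_entropy <- function(hm) {
  grid <- as_heatmap_grid(hm)
  -sum(xlog2x(grid))
}

#' Kullback-Leibler divergence between two heatmaps
#'
#' `KL(p || q) = sum_x p(x) log2(p(x) / q(x))` in bits; zero iff the maps are
#' identical. Used to check how closely the HMM-generated heatmap reproduces
#' the measured one. `q` must cover the support of `p` (smooth it with a
#' wide-enough kernel); pixels where `p > 0` but `q = 0` yield `Inf` with a
#' warning.
#'
#' @param p,q `gaze_heatmap` objects or normalized matrices of equal size.
#' @return Divergence in bits.
#' @export
heatmap_kl <- function(p, q) {
  gp <- as_heatmap_grid(p)
  gq <- as_heatmap_grid(q)
  if (!identical(dim(gp), dim(gq)))
    stop("heatmap dimensions differ: ", paste(dim(gp), collapse = "x"),
         " vs ", paste(dim(gq), collapse = "x"))
  sup <- gp > 0
  if (any(gq[sup] == 0)) {
    warning("support(p) not contained in support(q): KL is infinite")
    return(Inf)
  }
  sum(gp[sup] * (log2(gp[sup]) - log2(gq[sup])))
}
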