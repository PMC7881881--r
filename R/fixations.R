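#' Segment a gaze trajectory into fixations and saccades
#'
#' Two-state velocity HMM (identification by HMM): sample-to-sample speed is
#' modeled with a low-speed fixation state and a high-speed saccade state
#' (Rayleigh emissions), decoded by the Viterbi path. Consecutive
#' fixation-labeled samples merge into fixations; each jump between adjacent
#' fixations within one uninterrupted valid run yields a saccade whose
#' amplitude is the Euclidean distance between the flanking fixation
#' centroids. Fixations shorter than `min_fix_dur_s` are discarded. Invalid
#' runs longer than `max_gap_s` (default 75 ms) break the trajectory: no
#' fixation may span such a gap.
#'
#' @param traj a `gaze_trajectory` with at least 2 valid samples.
#' @param fix_speed,sac_speed Rayleigh scale (px/s) of the fixation and
#'   saccade speed distributions. Defaults suit 60 Hz data with a few px of
#'   within-fixation jitter; the implied speed boundary is ~1000 px/s.
#' @param min_fix_dur_s minimum fixation duration in seconds.
#' @param max_gap_s longest invalid gap a fixation may bridge, seconds.
#' @return An object of class `fixation_sequence`: a list with data frames
#'   `fixations` (`start_s`, `end_s`, `x_px`, `y_px`, `duration_ms`) and
#'   `saccades` (`onset_s`, `amplitude_px`).
#' @export
segment_fixations <- function(traj, fix_speed = 300, sac_speed = 6000,
                              min_fix_dur_s = 0.1, max_gap_s = 0.075) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  ok <- traj$valid
  if (sum(ok) < 2L) stop("need at least 2 valid samples to segment")
  t <- traj$t_s[ok]
  xy <- cbind(traj$x_px[ok], traj$y_px[ok])
  # Split into runs that contain no bridgeable-exceeding gap.
  seg_id <- cumsum(c(TRUE, diff(t) > max_gap_s))
  fix_list <- list()
  sac_list <- list()
  for (sid in unique(seg_id)) {
    idx <- which(seg_id == sid)
    if (length(idx) < 2L) next
    ts <- t[idx]
    ps <- xy[idx, , drop = FALSE]
    dt <- diff(ts)
    speed <- sqrt(rowSums(diff(ps)^2)) / dt
    labels <- viterbi_speed(speed, fix_speed, sac_speed)
    # labels[k] classifies the interval between samples k and k+1; a run of
    # fixation intervals a..b spans samples a..(b+1)
    runs <- rle(labels)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    seg_fix <- list()
    for (r in seq_along(runs$values)) {
      if (runs$values[r] != 1L) next
      sidx <- starts[r]:(ends[r] + 1L)
      dur <- ts[ends[r] + 1L] - ts[starts[r]]
      if (dur < min_fix_dur_s) next
      seg_fix[[length(seg_fix) + 1L]] <- data.frame(
        start_s = ts[starts[r]], end_s = ts[ends[r] + 1L],
        x_px = mean(ps[sidx, 1L]), y_px = mean(ps[sidx, 2L]))
    }
    if (length(seg_fix) == 0L) next
    seg_fix <- do.call(rbind, seg_fix)
    fix_list[[length(fix_list) + 1L]] <- seg_fix
    if (nrow(seg_fix) > 1L) {
      d <- sqrt(diff(seg_fix$x_px)^2 + diff(seg_fix$y_px)^2)
      sac_list[[length(sac_list) + 1L]] <- data.frame(
        onset_s = seg_fix$end_s[-nrow(seg_fix)], amplitude_px = d)
    }
  }
  fixations <- if (length(fix_list)) do.call(rbind, fix_list) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               x_px = numeric(0), y_px = numeric(0))
  saccades <- if (length(sac_list)) do.call(rbind, sac_list) else
    data.frame(onset_s = numeric(0), amplitude_px = numeric(0))
  fixations <- fixations[order(fixations$start_s), , drop = FALSE]
  rownames(fixations) <- NULL
  fixations$duration_ms <- (fixations$end_s - fixations$start_s) * 1000
  rownames(saccades) <- NULL
  structure(list(fixations = fixations, saccades = saccades),
            class = "fixation_sequence")
}

# Viterbi decoding of the speed sequence under two Rayleigh emission states
# (1 = fixation, 2 = saccade). Sticky fixation state, short-lived saccades.
viterbi_speed <- function(speed, fix_speed, sac_speed,
                          trans = matrix(c(0.95, 0.7, 0.05, 0.3), 2L),
                          init = c(0.9, 0.1)) {
  v <- pmax(speed, 1e-6)
  lrayleigh <- function(v, s) log(v) - 2 * log(s) - v^2 / (2 * s^2)
  logB <- cbind(lrayleigh(v, fix_speed), lrayleigh(v, sac_speed))
  n <- length(v)
  lt <- log(trans)
  delta <- matrix(-Inf, n, 2L)
  back <- matrix(1L, n, 2L)
  delta[1L, ] <- log(init) + logB[1L, ]
  if (n > 1L) for (k in 2L:n) {
    for (j in 1:2) {
      cand <- delta[k - 1L, ] + lt[, j]
      back[k, j] <- which.max(cand)
      delta[k, j] <- cand[back[k, j]] + logB[k, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (k in (n - 1L):1L) path[k] <- back[k + 1L, path[k + 1L]]
  path
}

#' @export
print.fixation_sequence <- function(x, ...) {
  cat(sprintf("<fixation_sequence> %d fixations, %d saccades\n",
              nrow(x$fixations), nrow(x$saccades)))
  invisible(x)
}

#' Summary statistics of a fixation sequence
#'
#' Mean fixation duration (a measure of focus) and mean saccade amplitude
#' (a measure of spatial exploration).
#'
#' @param fs a `fixation_sequence`.
#' @return A list with `mean_fixation_duration_ms`, `mean_saccade_amplitude_px`
#'   (`NA` when the sequence holds no saccade), `n_fixations`, `n_saccades`.
#' @export
gaze_summary <- function(fs) {
  stopifnot(inherits(fs, "fixation_sequence"))
  if (nrow(fs$fixations) == 0L) stop("no fixations in sequence")
  list(
    mean_fixation_duration_ms = mean(fs$fixations$duration_ms),
    mean_saccade_amplitude_px = if (nrow(fs$saccades)) mean(fs$saccades$amplitude_px) else NA_real_,
    n_fixations = nrow(fs$fixations),
    n_saccades = nrow(fs$saccades)
  )
}
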