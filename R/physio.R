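#' Locate R peaks in an ECG record (Pan-Tompkins)
#'
#' The classic QRS detection chain: band-pass 5-15 Hz, five-point
#' derivative, squaring, 150 ms moving-window integration, then adaptive
#' dual-threshold peak classification with a 200 ms refractory period and
#' search-back for missed beats when the gap exceeds 1.66 times the running
#' average RR. By default the band-pass runs zero-phase
#' (forward-backward) so detected beat times carry no filter delay; the
#' original causal filtering is available with `zero_phase = FALSE`. Each
#' accepted detection is refined to the local maximum of the raw signal so
#' the reported time sits on the R wave itself.
#'
#' @param ecg a `physio_record` with `channel = "ECG"`, at least 5 s long.
#' @param zero_phase logical; filter forward-backward (default) or causally.
#' @return Strictly increasing beat times in seconds (empty, with a warning,
#'   for a flat signal).
#' @export
detect_r_peaks <- function(ecg, zero_phase = TRUE) {
  stopifnot(inherits(ecg, "physio_record"))
  if (ecg$channel != "ECG") stop("detect_r_peaks needs an ECG record")
  fs <- ecg$rate
  x <- ecg$values
  if (length(x) / fs < 5) stop("record shorter than 5 s")
  if (max(x) - min(x) < 1e-9) {
    warning("flat ECG signal: no beats detected")
    return(numeric(0))
  }
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- if (zero_phase) signal::filtfilt(bf, x) else
    as.numeric(signal::filter(bf, x))
  # centered five-point derivative, squared, then centered 150 ms integration
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) * fs / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  win <- max(1L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  n <- length(integ)
  cand <- which(diff(sign(diff(integ))) < 0) + 1L   # local maxima
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0L) {
    warning("no candidate peaks found")
    return(numeric(0))
  }
  refr <- 0.2 * fs
  init_n <- min(n, round(2 * fs))
  spki <- max(integ[seq_len(init_n)]) * 0.5
  npki <- mean(integ[seq_len(init_n)]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_recent <- numeric(0)
  last_rejected <- integer(0)
  for (idx in cand) {
    if (length(qrs) && idx - qrs[length(qrs)] < refr) next
    h <- integ[idx]
    # search-back: long gap since the last beat, revisit rejected candidates
    if (length(qrs) && length(rr_recent) >= 2L) {
      rr_avg <- mean(rr_recent)
      if (idx - qrs[length(qrs)] > 1.66 * rr_avg && length(last_rejected)) {
        sb <- last_rejected[last_rejected > qrs[length(qrs)] + refr &
                              last_rejected < idx - refr]
        if (length(sb)) {
          best <- sb[which.max(integ[sb])]
          if (integ[best] > 0.5 * thr1) {
            spki <- 0.25 * integ[best] + 0.75 * spki
            rr_recent <- c(tail(rr_recent, 7L), best - qrs[length(qrs)])
            qrs <- c(qrs, best)
            last_rejected <- integer(0)
          }
        }
      }
    }
    if (h > thr1) {
      if (length(qrs)) rr_recent <- c(tail(rr_recent, 7L), idx - qrs[length(qrs)])
      qrs <- c(qrs, idx)
      spki <- 0.125 * h + 0.875 * spki
      last_rejected <- integer(0)
    } else {
      npki <- 0.125 * h + 0.875 * npki
      last_rejected <- c(last_rejected, idx)
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(qrs) == 0L) {
    warning("no beats crossed the adaptive threshold")
    return(numeric(0))
  }
  # refine each detection to the raw R wave within +/- 75 ms
  half <- round(0.075 * fs)
  ref <- vapply(qrs, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1L))
  ref <- sort(unique(ref))
  # enforce refractory after refinement (keep the larger raw peak)
  keep <- logical(length(ref))
  last <- -Inf
  for (k in seq_along(ref)) {
    if (ref[k] - last >= refr) {
      keep[k] <- TRUE
      last <- ref[k]
    } else if (x[ref[k]] > x[ref[which(keep)[sum(keep)]]]) {
      keep[which(keep)[sum(keep)]] <- FALSE
      keep[k] <- TRUE
      last <- ref[k]
    }
  }
  (ref[keep] - 1L) / fs
}

# RR intervals (seconds) whose both bounding beats fall inside [start, end).
rr_in_window <- function(beats, window) {
  inside <- beats >= window[1L] & beats < window[2L]
  b <- beats[inside]
  if (length(b) < 2L) return(numeric(0))
  diff(b)
}

#' Average heart rate in a window
#'
#' `60 * n / sum(RR)` over the RR intervals fully inside the half-open
#' window `[start, end)`, i.e. 60 divided by the mean RR in seconds.
#'
#' @param beats beat times in seconds.
#' @param window `c(start, end)` in seconds.
#' @return Heart rate in bpm, or `NA` (flagged undefined) with fewer than
#'   2 beats in the window.
#' @export
heart_rate <- function(beats, window) {
  rr <- rr_in_window(beats, window)
  if (length(rr) < 1L) return(NA_real_)
  60 * length(rr) / sum(rr)
}

#' RMSSD heart-rate variability in a window
#'
#' Root mean square of successive RR-interval differences, in ms, over the
#' beats inside the half-open window. A time-domain index of
#' parasympathetic activity; higher values indicate more relaxation.
#'
#' @inheritParams heart_rate
#' @return RMSSD in ms, or `NA` with fewer than 3 beats in the window.
#' @export
rmssd <- function(beats, window) {
  rr <- rr_in_window(beats, window)
  if (length(rr) < 2L) return(NA_real_)
  sqrt(mean(diff(rr * 1000)^2))
}

#' Mean skin conductance level in a window
#'
#' Arithmetic mean of the GSR samples inside the half-open window; the tonic
#' electrodermal level, an index of sympathetic arousal.
#'
#' @param gsr a `physio_record` with `channel = "GSR"`.
#' @param window `c(start, end)` in seconds (record time starts at 0).
#' @return SCL in microsiemens, or `NA` for an empty window.
#' @export
scl <- function(gsr, window) {
  stopifnot(inherits(gsr, "physio_record"))
  if (gsr$channel != "GSR") stop("scl needs a GSR record")
  t <- (seq_along(gsr$values) - 1L) / gsr$rate
  inside <- t >= window[1L] & t < window[2L]
  if (!any(inside)) return(NA_real_)
  mean(gsr$values[inside])
}

#' Per-window physiological metrics
#'
#' HR, RMSSD and SCL over one window.
#'
#' @param beats beat times in seconds.
#' @param gsr a GSR `physio_record` (or `NULL` to skip SCL).
#' @param window `c(start, end)` seconds.
#' @return A list with `hr`, `rmssd`, `scl` and `window`.
#' @export
physio_metrics <- function(beats, gsr, window) {
  list(hr = heart_rate(beats, window),
       rmssd = rmssd(beats, window),
       scl = if (is.null(gsr)) NA_real_ else scl(gsr, window),
       window = window)
}

#' Baseline-relative deltas
#'
#' Subtracts the 3-minute baseline value of each metric from its per-window
#' values, producing the ΔHR / ΔRMSSD / ΔSCL series. Undefined (`NA`)
#' inputs propagate as `NA`.
#'
#' @param metrics data frame with columns `hr`, `rmssd`, `scl`, one row per
#'   window (or a list as returned by [physio_metrics()]).
#' @param baseline a list/row with `hr`, `rmssd`, `scl` from the baseline
#'   period.
#' @return Data frame with columns `d_hr`, `d_rmssd`, `d_scl`.
#' @export
baseline_deltas <- function(metrics, baseline) {
  if (!is.data.frame(metrics)) metrics <- as.data.frame(metrics[c("hr", "rmssd", "scl")])
  data.frame(d_hr = metrics$hr - baseline$hr,
             d_rmssd = metrics$rmssd - baseline$rmssd,
             d_scl = metrics$scl - baseline$scl)
}
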