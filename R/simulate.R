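#' Session configuration
#'
#' Bundle of acquisition constants for one recording session, defaulting to
#' the study conditions: a 960 x 720 px scene image, 60 Hz gaze sampling,
#' 2048 Hz ECG, 256 Hz GSR, a 3-minute baseline followed by 15 minutes of
#' viewing, and ~20% gaze dropout from blinks and off-scene glances.
#'
#' @param image_width,image_height scene-image size in pixels.
#' @param gaze_rate,ecg_rate,gsr_rate sampling rates in Hz.
#' @param baseline_duration,viewing_duration segment lengths in seconds.
#' @param dropout_fraction fraction of gaze samples flagged invalid, in `[0, 1)`.
#' @param seed integer root seed for the session.
#' @return A list of class `session_config`.
#' @export
session_config <- function(image_width = 960L, image_height = 720L,
                           gaze_rate = 60, ecg_rate = 2048, gsr_rate = 256,
                           baseline_duration = 180, viewing_duration = 900,
                           dropout_fraction = 0.20, seed = NULL) {
  stopifnot(gaze_rate > 0, ecg_rate > 0, gsr_rate > 0,
            baseline_duration > 0, viewing_duration > 0,
            dropout_fraction >= 0, dropout_fraction < 1,
            image_width > 0, image_height > 0)
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 gaze_rate = gaze_rate, ecg_rate = ecg_rate,
                 gsr_rate = gsr_rate,
                 baseline_duration = baseline_duration,
                 viewing_duration = viewing_duration,
                 dropout_fraction = dropout_fraction, seed = seed),
            class = "session_config")
}

# Mark `target` of `n` samples invalid in contiguous blink-like runs whose
# mean length is `mean_run` samples, at positions spread uniformly over the
# record. The realized invalid count equals `target` exactly.
dropout_mask <- function(n, fraction, mean_run = 12L) {
  target <- round(fraction * n)
  if (target == 0L) return(rep(TRUE, n))
  runs <- integer(0)
  while (sum(runs) < target) {
    runs <- c(runs, 1L + stats::rgeom(1L, 1 / mean_run))
  }
  runs[length(runs)] <- runs[length(runs)] - (sum(runs) - target)
  runs <- runs[runs > 0L]
  k <- length(runs)
  free <- n - target
  cuts <- sort(sample.int(free + 1L, k, replace = TRUE)) - 1L
  gaps <- c(cuts[1L], diff(cuts), free - cuts[k])
  valid <- rep(TRUE, n)
  pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    valid[(pos + 1L):(pos + runs[i])] <- FALSE
    pos <- pos + runs[i]
  }
  valid
}

#' Simulate a gaze trajectory from a two-state scanpath HMM
#'
#' State dynamics run at fixation granularity: each fixation draws its state
#' from the Markov chain, its centroid from the state's emission GMM, and
#' its duration from a gamma distribution with the requested mean; samples
#' within a fixation jitter isotropically around the centroid and the jump
#' to the next fixation is instantaneous (one-sample transition, which is
#' all 60 Hz can resolve). Dropout is placed in contiguous blink-like runs
#' (mean 200 ms). Ground-truth labels are returned for recovery tests.
#'
#' @param hmm a `gaze_hmm`; all emission component means must lie inside the
#'   image frame.
#' @param config a [session_config()].
#' @param fixation_duration_mean mean fixation duration in ms (gamma law,
#'   shape 4).
#' @param seed integer seed.
#' @param duration length of the simulated segment in s; defaults to
#'   `config$viewing_duration`.
#' @param jitter_sd within-fixation isotropic jitter SD, px.
#' @return A list of class `gaze_session`: `traj` (a [gaze_trajectory]),
#'   `states` (true state per fixation), `fixations` (data frame
#'   `start_s`, `end_s`, `x_px`, `y_px`, `state`), and `config`.
#' @export
simulate_gaze <- function(hmm, config = session_config(),
                          fixation_duration_mean = 350, seed = NULL,
                          duration = config$viewing_duration,
                          jitter_sd = 3) {
  stopifnot(inherits(hmm, "gaze_hmm"))
  dims <- c(config$image_width, config$image_height)
  for (s in 1:2) {
    mu <- hmm$emissions[[s]]$means
    if (any(mu[, 1L] < 0 | mu[, 1L] >= dims[1L] |
              mu[, 2L] < 0 | mu[, 2L] >= dims[2L]))
      stop("emission component mean outside the image frame in state ", s)
  }
  with_seed(seed, {
    shape <- 4
    mean_s <- fixation_duration_mean / 1000
    n_guess <- ceiling(duration / mean_s * 1.3) + 10L
    durs <- rgamma(n_guess, shape = shape, rate = shape / mean_s)
    while (sum(durs) < duration)
      durs <- c(durs, rgamma(n_guess, shape = shape, rate = shape / mean_s))
    n_fix <- which(cumsum(durs) >= duration)[1L]
    durs <- durs[seq_len(n_fix)]
    starts <- cumsum(c(0, durs[-n_fix]))
    ends <- pmin(starts + durs, duration)

    states <- integer(n_fix)
    states[1L] <- sample.int(2L, 1L, prob = hmm$p)
    if (n_fix > 1L) for (i in 2L:n_fix)
      states[i] <- sample.int(2L, 1L, prob = hmm$A[states[i - 1L], ])

    centroids <- matrix(0, n_fix, 2L)
    for (s in 1:2) {
      idx <- which(states == s)
      if (!length(idx)) next
      draw <- gmm_sample(hmm$emissions[[s]], length(idx))
      # redraw out-of-frame points a few times, then clamp
      for (r in 1:20) {
        out <- draw[, 1L] < 0 | draw[, 1L] >= dims[1L] |
          draw[, 2L] < 0 | draw[, 2L] >= dims[2L]
        if (!any(out)) break
        draw[out, ] <- gmm_sample(hmm$emissions[[s]], sum(out))
      }
      centroids[idx, ] <- draw
    }
    centroids[, 1L] <- pmin(pmax(centroids[, 1L], 0), dims[1L] - 1e-6)
    centroids[, 2L] <- pmin(pmax(centroids[, 2L], 0), dims[2L] - 1e-6)

    dt <- 1 / config$gaze_rate
    t_s <- seq(0, duration - dt / 2, by = dt)
    fix_of <- findInterval(t_s, starts)
    xy <- centroids[fix_of, , drop = FALSE] +
      matrix(rnorm(2L * length(t_s), 0, jitter_sd), ncol = 2L)
    xy[, 1L] <- pmin(pmax(xy[, 1L], 0), dims[1L] - 1e-6)
    xy[, 2L] <- pmin(pmax(xy[, 2L], 0), dims[2L] - 1e-6)
    valid <- dropout_mask(length(t_s), config$dropout_fraction,
                          mean_run = max(1L, round(0.2 * config$gaze_rate)))
    traj <- gaze_trajectory(t_s, xy[, 1L], xy[, 2L], valid, image_dims = dims)
    structure(list(traj = traj, states = states,
                   fixations = data.frame(start_s = starts, end_s = ends,
                                          x_px = centroids[, 1L],
                                          y_px = centroids[, 2L],
                                          state = states),
                   config = config),
              class = "gaze_session")
  })
}

# Synthetic PQRST complex: sum of Gaussians at offsets (s) from the R wave.
pqrst_template <- function(t_rel) {
  amps <- c(P = 0.12, Q = -0.10, R = 1.00, S = -0.18, T = 0.35)
  mus <- c(P = -0.200, Q = -0.028, R = 0.000, S = 0.028, T = 0.260)
  sds <- c(P = 0.028, Q = 0.010, R = 0.010, S = 0.012, T = 0.050)
  out <- numeric(length(t_rel))
  for (k in seq_along(amps)) out <- out + amps[k] * exp(-(t_rel - mus[k])^2 / (2 * sds[k]^2))
  out
}

#' Simulate an ECG record with known beat times
#'
#' RR intervals are `mean_rr` plus zero-mean Gaussian perturbations, scaled
#' so the realized RMSSD of the generated RR series equals `rmssd_target`
#' exactly; a synthetic PQRST template (sum of Gaussians) is placed at each
#' beat. Serves as the oracle for QRS detection and RMSSD recovery.
#'
#' @param mean_rr mean RR interval in ms; must exceed `2 * rmssd_target`.
#' @param rmssd_target target RMSSD in ms (0 gives perfectly regular beats).
#' @param duration record length in s.
#' @param rate sampling rate in Hz (>= 100 to resolve the QRS complex).
#' @param seed integer seed.
#' @param noise_sd additive Gaussian noise SD (mV), default 0 (clean).
#' @return A list with `record` (an ECG [physio_record]) and `beat_times`
#'   (exact R-wave times in s).
#' @export
simulate_ecg <- function(mean_rr = 1000, rmssd_target = 30, duration = 300,
                         rate = 2048, seed = NULL, noise_sd = 0) {
  stopifnot(duration > 0)
  if (rate < 100) stop("sampling rate below 100 Hz cannot resolve the QRS complex")
  if (mean_rr <= 2 * rmssd_target)
    stop("mean_rr must exceed 2 * rmssd_target")
  with_seed(seed, {
    n_rr <- ceiling(duration * 1000 / mean_rr) + 3L
    if (rmssd_target > 0) {
      e <- rnorm(n_rr)
      sc <- rmssd_target / sqrt(mean(diff(e)^2))
      rr <- mean_rr + sc * e
    } else {
      rr <- rep(mean_rr, n_rr)
    }
    first <- 0.4
    beats <- first + cumsum(c(0, rr[-n_rr])) / 1000
    beats <- beats[beats < duration - 0.35]
    n <- round(duration * rate)
    t <- (seq_len(n) - 1L) / rate
    x <- numeric(n)
    half <- 0.45
    for (b in beats) {
      lo <- max(1L, floor((b - half) * rate) + 1L)
      hi <- min(n, ceiling((b + half) * rate) + 1L)
      x[lo:hi] <- x[lo:hi] + pqrst_template(t[lo:hi] - b)
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    list(record = physio_record(x, rate, "ECG"), beat_times = beats,
         rr_ms = diff(beats) * 1000)
  })
}

#' Simulate a tonic skin-conductance record
#'
#' Tonic level plus linear drift plus low-amplitude Gaussian noise; window
#' means are recoverable in closed form (`L + slope * T / 2` over `[0, T]`).
#'
#' @param scl_level tonic level in microsiemens (nonnegative).
#' @param drift_slope linear drift in microsiemens per minute.
#' @param duration record length in s.
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @param noise_sd additive noise SD in microsiemens.
#' @return A GSR [physio_record].
#' @export
simulate_gsr <- function(scl_level = 5, drift_slope = 0, duration = 300,
                         rate = 256, seed = NULL, noise_sd = 0.05) {
  if (scl_level < 0) stop("scl_level must be nonnegative")
  stopifnot(duration > 0, rate > 0)
  with_seed(seed, {
    t <- (seq_len(round(duration * rate)) - 1L) / rate
    v <- scl_level + drift_slope * t / 60 +
      (if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0)
    physio_record(pmax(v, 0), rate, "GSR")
  })
}

#' Coupling slope giving a target population correlation
#'
#' With per-window transition entropy H ~ N(mu, sd_te^2) and
#' `dHR = slope * (H - mu) + eps`, `eps ~ N(0, sd_noise^2)`, the population
#' Pearson correlation between H and dHR is
#' `r = slope * sd_te / sqrt(slope^2 sd_te^2 + sd_noise^2)`; this inverts
#' that relation.
#'
#' @param r target correlation in `(-1, 1)`.
#' @param sd_te SD of transition entropy across windows (bits).
#' @param sd_noise SD of the uncoupled dHR noise (bpm).
#' @return Slope in bpm per bit.
#' @export
coupling_slope_for_r <- function(r, sd_te = 0.17, sd_noise = 3) {
  stopifnot(abs(r) < 1)
  r / sqrt(1 - r^2) * sd_noise / sd_te
}

default_cohort_means <- function() {
  list(transition_entropy = 0.47, spatial_entropy = 16.3,
       fixation_duration = 370, saccade_amplitude = 110,
       d_hr = 0, d_rmssd = 0, d_scl = 0)
}

default_cohort_sds <- function() {
  list(transition_entropy = 0.17, spatial_entropy = 0.7,
       fixation_duration = 150, saccade_amplitude = 30,
       d_hr = 3, d_rmssd = 8, d_scl = 0.5)
}

#' Simulate a multi-subject cohort of windowed metrics
#'
#' Generates the per-subject, per-scene, per-window metric table the
#' inferential stages consume, with known ground truth. Two levels:
#' `"metrics"` (default) draws the windowed gaze metrics and physiology
#' deltas directly from the generative model — transition entropy and ΔHR
#' are linked through `coupling_slope` plus Gaussian noise, so the pooled
#' Pearson correlation has the known population value of
#' [coupling_slope_for_r()]'s relation — and is cheap enough for
#' repeated-simulation calibration. `"sessions"` additionally generates the
#' full raw gaze and physiology signals per subject for end-to-end tests
#' (see [simulate_session()]).
#'
#' Additive group shifts are injected per factor level through
#' `effect_sizes`, a named list mapping a metric name to a vector with any
#' of the entries `scene` (added for the second scene level), `gender`
#' (added for females) and `modality` (added for `"photo"`).
#'
#' @param n_subjects number of subjects (default 38, of which `n_female`).
#' @param n_female number of female subjects (default 11).
#' @param scenes,modalities factor levels; every subject contributes every
#'   scene x modality cell.
#' @param n_windows viewing windows per session (default 5).
#' @param coupling_slope ΔHR change per bit of transition entropy.
#' @param effect_sizes named list of per-factor additive shifts (see above).
#' @param seed integer root seed.
#' @param level `"metrics"` or `"sessions"`.
#' @param config a [session_config()] (sessions level only).
#' @return A list of class `cohort`: `metrics` (tibble, one row per subject
#'   x scene x modality x window), `truth` (generator bookkeeping: the
#'   population coupling slope, means/SDs used, expected pooled r), and for
#'   sessions level `sessions`, a list of raw session objects.
#' @export
simulate_cohort <- function(n_subjects = 38L, n_female = 11L,
                            scenes = c("courtyard", "garden"),
                            modalities = "direct", n_windows = 5L,
                            coupling_slope = 0, effect_sizes = list(),
                            seed = NULL, level = c("metrics", "sessions"),
                            config = session_config()) {
  level <- match.arg(level)
  stopifnot(n_subjects >= 2L, n_female <= n_subjects)
  mu <- default_cohort_means()
  sdv <- default_cohort_sds()
  with_seed(seed, {
    gender <- c(rep("F", n_female), rep("M", n_subjects - n_female))
    grid <- expand.grid(window_index = seq_len(n_windows), scene = scenes,
                        modality = modalities,
                        subject = seq_len(n_subjects),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("subject", "scene", "modality", "window_index")]
    grid$gender <- gender[grid$subject]
    n <- nrow(grid)
    shift <- function(metric) {
      es <- effect_sizes[[metric]]
      out <- numeric(n)
      if (is.null(es)) return(out)
      if ("scene" %in% names(es) && length(scenes) > 1L)
        out <- out + ifelse(grid$scene == scenes[2L], es[["scene"]], 0)
      if ("gender" %in% names(es))
        out <- out + ifelse(grid$gender == "F", es[["gender"]], 0)
      if ("modality" %in% names(es) && length(modalities) > 1L)
        out <- out + ifelse(grid$modality == "photo", es[["modality"]], 0)
      out
    }
    te <- mu$transition_entropy + shift("transition_entropy") +
      rnorm(n, 0, sdv$transition_entropy)
    te <- pmin(pmax(te, 0), 1)
    d_hr <- coupling_slope * (te - mu$transition_entropy) +
      shift("d_hr") + rnorm(n, 0, sdv$d_hr)
    tbl <- tibble::tibble(
      subject = grid$subject, scene = grid$scene, modality = grid$modality,
      gender = grid$gender, window_index = grid$window_index,
      fixation_duration = mu$fixation_duration + shift("fixation_duration") +
        rnorm(n, 0, sdv$fixation_duration),
      saccade_amplitude = pmax(mu$saccade_amplitude + shift("saccade_amplitude") +
                                 rnorm(n, 0, sdv$saccade_amplitude), 1),
      spatial_entropy = mu$spatial_entropy + shift("spatial_entropy") +
        rnorm(n, 0, sdv$spatial_entropy),
      transition_entropy = te,
      d_hr = d_hr,
      d_rmssd = mu$d_rmssd + shift("d_rmssd") + rnorm(n, 0, sdv$d_rmssd),
      d_scl = mu$d_scl + shift("d_scl") + rnorm(n, 0, sdv$d_scl))
    truth <- list(coupling_slope = coupling_slope, means = mu, sds = sdv,
                  expected_r = coupling_slope * sdv$transition_entropy /
                    sqrt((coupling_slope * sdv$transition_entropy)^2 + sdv$d_hr^2))
    sessions <- NULL
    if (level == "sessions") {
      sub_seeds <- sample.int(2^31 - 2L, n_subjects)
      sessions <- lapply(seq_len(n_subjects), function(s) {
        simulate_session(config = config, seed = sub_seeds[s],
                         coupling_slope = coupling_slope)
      })
    }
    structure(list(metrics = tbl, truth = truth, sessions = sessions),
              class = "cohort")
  })
}

#' Default two-state scanpath model used by the generator
#'
#' A compact central state (near the image center) and a dispersed
#' peripheral state whose components ring the frame, with a sticky central
#' state — the qualitative regime observed for prolonged scene viewing.
#'
#' @param A transition matrix (default `[[0.9, 0.1], [0.3, 0.7]]`).
#' @param dims image dimensions `c(width, height)`.
#' @return A `gaze_hmm`.
#' @export
default_gaze_hmm <- function(A = matrix(c(0.9, 0.3, 0.1, 0.7), 2L),
                             dims = c(960L, 720L)) {
  ctr <- dims / 2
  central <- gaussian_mixture(
    weights = c(0.6, 0.4),
    means = rbind(ctr + c(-40, 0), ctr + c(50, 20)),
    covs = array(rep(diag(c(3600, 2500)), 2L), c(2L, 2L, 2L)))
  ring <- rbind(c(0.18, 0.2), c(0.5, 0.12), c(0.82, 0.2),
                c(0.15, 0.75), c(0.85, 0.75), c(0.5, 0.85))
  pm <- cbind(ring[, 1L] * dims[1L], ring[, 2L] * dims[2L])
  peripheral <- gaussian_mixture(
    weights = rep(1 / 6, 6L),
    means = pm,
    covs = array(rep(diag(c(4900, 3600)), 6L), c(2L, 2L, 6L)))
  pi_ <- steady_state(A)
  gaze_hmm(A, pi_, list(central, peripheral))
}

#' Simulate one full synchronized session
#'
#' Raw gaze plus ECG plus GSR for a baseline segment followed by a viewing
#' segment, with per-window ground truth. The viewing segment's heart
#' period is modulated per window as a linear function of that window's
#' generating transition entropy (`coupling_slope`, bpm per bit), inducing
#' the designed gaze-physiology coupling in the raw signals.
#'
#' @param config a [session_config()].
#' @param hmm generating `gaze_hmm`; defaults to [default_gaze_hmm()].
#' @param seed integer seed.
#' @param coupling_slope bpm of ΔHR per bit of transition entropy.
#' @param baseline_hr baseline heart rate, bpm.
#' @param rmssd_target RMSSD in ms for every segment.
#' @param scl_level,scl_drift GSR level (µS) and drift (µS/min).
#' @param te_sd SD of the per-window generating transition entropy (bits).
#' @return A list of class `session`: `gaze` (viewing `gaze_session`),
#'   `ecg`, `gsr` (records spanning baseline + viewing), `beat_times`,
#'   `windows` (data frame of window bounds, seconds from viewing onset),
#'   and `truth` (per-window generating A, transition entropy and ΔHR).
#' @export
simulate_session <- function(config = session_config(),
                             hmm = default_gaze_hmm(dims = c(config$image_width, config$image_height)),
                             seed = NULL, coupling_slope = 0,
                             baseline_hr = 70, rmssd_target = 30,
                             scl_level = 5, scl_drift = 0.05,
                             te_sd = 0.1) {
  with_seed(seed, {
    n_windows <- max(1L, floor(config$viewing_duration / 180))
    base_A <- hmm$A
    base_te <- transition_entropy(base_A)
    # per-window generating chain: scale the off-diagonal rates to move the
    # entropy around its base value
    win_A <- vector("list", n_windows)
    win_te <- numeric(n_windows)
    for (wdx in seq_len(n_windows)) {
      f <- exp(rnorm(1L, 0, te_sd / max(base_te, 0.1)))
      A <- base_A
      A[1L, 2L] <- min(max(base_A[1L, 2L] * f, 0.02), 0.95)
      A[2L, 1L] <- min(max(base_A[2L, 1L] * f, 0.02), 0.95)
      A[1L, 1L] <- 1 - A[1L, 2L]
      A[2L, 2L] <- 1 - A[2L, 1L]
      win_A[[wdx]] <- A
      win_te[wdx] <- transition_entropy(A)
    }
    seeds <- sample.int(2^31 - 2L, n_windows + 4L)
    # gaze: simulate each viewing window with its own chain, then stitch
    win_len <- config$viewing_duration / n_windows
    parts <- lapply(seq_len(n_windows), function(wdx) {
      h <- hmm; h$A <- win_A[[wdx]]; h$p <- steady_state(win_A[[wdx]])
      simulate_gaze(h, config, seed = seeds[wdx], duration = win_len)
    })
    dt <- 1 / config$gaze_rate
    traj <- do.call(rbind, lapply(seq_len(n_windows), function(wdx) {
      tr <- parts[[wdx]]$traj
      tr$t_s <- tr$t_s + (wdx - 1L) * win_len
      as.data.frame(tr)
    }))
    gaze_traj <- gaze_trajectory(traj$t_s, traj$x_px, traj$y_px, traj$valid,
                                 image_dims = c(config$image_width, config$image_height))
    fixations <- do.call(rbind, lapply(seq_len(n_windows), function(wdx) {
      fx <- parts[[wdx]]$fixations
      fx$start_s <- fx$start_s + (wdx - 1L) * win_len
      fx$end_s <- fx$end_s + (wdx - 1L) * win_len
      fx$window_index <- wdx
      fx
    }))
    gaze <- structure(list(traj = gaze_traj, states = fixations$state,
                           fixations = fixations, config = config),
                      class = "gaze_session")
    # ECG: baseline at baseline_hr, then per-window HR modulated by entropy
    d_hr_true <- coupling_slope * (win_te - base_te)
    total_dur <- config$baseline_duration + config$viewing_duration
    seg_hr <- c(baseline_hr, baseline_hr + d_hr_true)
    seg_len <- c(config$baseline_duration, rep(win_len, n_windows))
    seg_parts <- lapply(seq_along(seg_hr), function(k) {
      simulate_ecg(mean_rr = 60000 / seg_hr[k], rmssd_target = rmssd_target,
                   duration = seg_len[k], rate = config$ecg_rate,
                   seed = seeds[n_windows + 1L] + k)
    })
    offs <- cumsum(c(0, seg_len[-length(seg_len)]))
    ecg_values <- unlist(lapply(seg_parts, function(p) p$record$values))
    beat_times <- unlist(lapply(seq_along(seg_parts),
                                function(k) seg_parts[[k]]$beat_times + offs[k]))
    ecg <- physio_record(ecg_values, config$ecg_rate, "ECG")
    gsr <- simulate_gsr(scl_level, scl_drift, total_dur, config$gsr_rate,
                        seed = seeds[n_windows + 2L])
    windows <- data.frame(window_index = seq_len(n_windows),
                          start_s = (seq_len(n_windows) - 1L) * win_len,
                          end_s = seq_len(n_windows) * win_len)
    structure(list(gaze = gaze, ecg = ecg, gsr = gsr,
                   beat_times = beat_times, windows = windows,
                   truth = list(win_A = win_A, transition_entropy = win_te,
                                d_hr = d_hr_true, base_A = base_A,
                                rmssd = rmssd_target, scl_level = scl_level,
                                scl_drift = scl_drift,
                                coupling_slope = coupling_slope)),
              class = "session")
  })
}
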