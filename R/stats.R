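#' Build the per-window joint metrics table
#'
#' Joins gaze metrics (fixation duration, saccade amplitude, spatial
#' entropy, transition entropy) and physiology deltas (ΔHR, ΔRMSSD, ΔSCL)
#' into one row per subject x scene x modality x window. For a
#' metrics-level cohort this validates and returns the generator's table;
#' for a sessions-level cohort it runs the full measurement pipeline on the
#' raw signals of every session (see [analyze_session()]). Rows carrying a
#' flagged-missing (`NA`) metric are excluded, with the count reported via
#' `message()`.
#'
#' @param cohort a `cohort` from [simulate_cohort()], or a data frame
#'   already shaped like the windowed table.
#' @param ... passed to [analyze_session()] for sessions-level cohorts.
#' @return A tibble of complete windowed metrics; the number of excluded
#'   rows is attached as attribute `n_excluded`.
#' @export
build_window_table <- function(cohort, ...) {
  if (inherits(cohort, "cohort") && is.null(cohort$sessions)) {
    tbl <- cohort$metrics
  } else if (inherits(cohort, "cohort")) {
    rows <- lapply(seq_along(cohort$sessions), function(s) {
      out <- analyze_session(cohort$sessions[[s]], ...)
      out$subject <- s
      out$gender <- cohort$metrics$gender[match(s, cohort$metrics$subject)]
      out
    })
    tbl <- do.call(rbind, rows)
    tbl <- tibble::as_tibble(tbl)
  } else {
    tbl <- tibble::as_tibble(cohort)
  }
  metric_cols <- intersect(
    c("fixation_duration", "saccade_amplitude", "spatial_entropy",
      "transition_entropy", "d_hr", "d_rmssd", "d_scl"), names(tbl))
  complete <- stats::complete.cases(tbl[, metric_cols])
  n_excluded <- sum(!complete)
  if (n_excluded > 0L)
    message(n_excluded, " window row(s) excluded for flagged-missing metrics")
  out <- tbl[complete, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Run the measurement pipeline on one raw session
#'
#' Per 3-minute viewing window: segment fixations, summarize duration and
#' amplitude, compute the heatmap spatial entropy, re-estimate the
#' transition matrix under the session-level (or supplied) HMM and take its
#' transition entropy; detect beats over the whole record, compute HR /
#' RMSSD / SCL per window and express them relative to the 3-minute
#' baseline.
#'
#' @param session a `session` from [simulate_session()].
#' @param hmm optional subject-independent `gaze_hmm`; when `NULL` one is
#'   fit to this session's fixation centroids.
#' @param sigma heatmap kernel SD in px.
#' @param seed seed for the HMM initialization when `hmm` is `NULL`.
#' @return Data frame, one row per window, with the joint gaze/physio
#'   metrics.
#' @export
analyze_session <- function(session, hmm = NULL, sigma = 10, seed = 1L) {
  stopifnot(inherits(session, "session"))
  cfg <- session$gaze$config
  traj <- session$gaze$traj
  fs <- segment_fixations(traj)
  cent <- fixation_obs(fs)
  if (is.null(hmm)) {
    init <- init_gaze_hmm(cent, n_central = 2L, n_peripheral = 6L,
                          dims = c(cfg$image_width, cfg$image_height),
                          seed = seed)
    hmm <- train_hmm(cent, init)
  }
  beats <- detect_r_peaks(session$ecg)
  base_win <- c(0, cfg$baseline_duration)
  base <- physio_metrics(beats, session$gsr, base_win)
  off <- cfg$baseline_duration
  rows <- lapply(seq_len(nrow(session$windows)), function(w) {
    win <- c(session$windows$start_s[w], session$windows$end_s[w])
    in_win <- fs$fixations$start_s >= win[1L] & fs$fixations$start_s < win[2L]
    wfix <- fs$fixations[in_win, , drop = FALSE]
    sac_in <- fs$saccades$onset_s >= win[1L] & fs$saccades$onset_s < win[2L]
    tr_w <- traj[traj$t_s >= win[1L] & traj$t_s < win[2L], , drop = FALSE]
    attr(tr_w, "image_dims") <- image_dims(traj)
    class(tr_w) <- class(traj)
    hm <- compute_heatmap(tr_w, sigma = sigma)
    wobs <- cent[in_win, , drop = FALSE]
    attr(wobs, "seq") <- obs_seq(cent)[in_win]
    A_w <- reestimate_transitions(hmm, wobs)
    pm <- physio_metrics(beats, session$gsr, off + win)
    data.frame(
      scene = "synthetic", modality = "direct", window_index = w,
      fixation_duration = if (nrow(wfix)) mean(wfix$duration_ms) else NA_real_,
      saccade_amplitude = if (any(sac_in)) mean(fs$saccades$amplitude_px[sac_in]) else NA_real_,
      spatial_entropy = spatial_entropy(hm),
      transition_entropy = transition_entropy(A_w),
      d_hr = pm$hr - base$hr,
      d_rmssd = pm$rmssd - base$rmssd,
      d_scl = pm$scl - base$scl)
  })
  do.call(rbind, rows)
}

#' Pooled Pearson correlation over windowed observations
#'
#' Pearson correlation with the two-sided p-value from the t distribution
#' on `n - 2` degrees of freedom. Windows are pooled as independent
#' observations by default; pass `aggregate_by` (e.g. subject ids) to
#' average within groups first.
#'
#' @param x,y numeric metric columns of equal length (`NA` pairs dropped).
#' @param aggregate_by optional grouping vector; when given, `x` and `y`
#'   are averaged per group before correlating.
#' @return A list with `r`, `p`, `n`.
#' @export
pooled_correlation <- function(x, y, aggregate_by = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(aggregate_by)) {
    g <- aggregate_by[ok]
    x <- tapply(x, g, mean)
    y <- tapply(y, g, mean)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observation pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Two-by-two factorial ANOVA with partial eta squared
#'
#' Fits `values ~ A * B` with sum-to-zero contrasts and Type-III sums of
#' squares (robust to the unbalanced gender cells), returning F, p and
#' partial eta squared `SS_effect / (SS_effect + SS_error)` for each main
#' effect and the interaction. Effect-size anchors: 0.01 small, 0.06
#' medium, 0.14 large. With one degree of freedom per effect, the Type-III
#' sum of squares is `b_j^2 / [(X'X)^{-1}]_jj` for the effect's sum-contrast
#' coefficient, which stays defined even when the within-cell variance is
#' zero; Type-II is computed from nested residual sums of squares.
#'
#' @param values numeric response vector.
#' @param factor_a,factor_b factors with exactly two levels each.
#' @param ss_type `"III"` (default) or `"II"`.
#' @return A tibble with columns `effect`, `df`, `ss`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
anova_2x2 <- function(values, factor_a, factor_b, ss_type = c("III", "II")) {
  ss_type <- match.arg(ss_type)
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  if (nlevels(fa) != 2L || nlevels(fb) != 2L)
    stop("both factors must have exactly 2 levels")
  tab <- table(fa, fb)
  if (any(tab < 2L)) stop("every cell needs at least 2 observations")
  dat <- data.frame(y = values, A = fa, B = fb)
  ctr <- list(A = "contr.sum", B = "contr.sum")
  mod <- lm(y ~ A * B, data = dat, contrasts = ctr)
  ss_err <- sum(stats::residuals(mod)^2)
  df_err <- stats::df.residual(mod)
  if (ss_type == "III") {
    b <- stats::coef(mod)[c("A1", "B1", "A1:B1")]
    cu <- suppressWarnings(summary(mod))$cov.unscaled
    ss <- b^2 / diag(cu)[c("A1", "B1", "A1:B1")]
  } else {
    rss <- function(f, cn) sum(stats::residuals(lm(f, data = dat,
                                                   contrasts = ctr[cn]))^2)
    rss_ab <- rss(y ~ A + B, c("A", "B"))
    ss <- c(rss(y ~ B, "B") - rss_ab,
            rss(y ~ A, "A") - rss_ab,
            rss_ab - ss_err)
  }
  ss <- pmax(unname(ss), 0)
  df <- c(1, 1, 1)
  Fv <- (ss / df) / (ss_err / df_err)
  p <- stats::pf(Fv, df, df_err, lower.tail = FALSE)
  tibble::tibble(
    effect = c("A", "B", "A:B"), df = df, ss = ss, F = Fv, p = p,
    partial_eta_sq = ifelse(ss + ss_err > 0, ss / (ss + ss_err), 0))
}

#' Mixture-count robustness sweep of the entropy-ΔHR correlation
#'
#' Re-runs the HMM stage with the per-state mixture counts scaled by each
#' factor (counts rounded, floored at 1), re-estimates the per-window
#' transition matrices, and reports the pooled correlation between
#' transition entropy and ΔHR per setting.
#'
#' @param cohort a sessions-level `cohort` from [simulate_cohort()].
#' @param mixture_factors numeric factors applied to the component counts.
#' @param n_central,n_peripheral base mixture counts per state.
#' @param seed seed for HMM initializations.
#' @return A tibble with `factor`, `n_central`, `n_peripheral`, `r`, `p`, `n`.
#' @export
robustness_sweep <- function(cohort, mixture_factors = c(0.75, 1, 1.25),
                             n_central = 2L, n_peripheral = 6L, seed = 1L) {
  if (length(mixture_factors) == 0L) stop("mixture_factors must be non-empty")
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$sessions))
  cfg <- cohort$sessions[[1L]]$gaze$config
  dims <- c(cfg$image_width, cfg$image_height)
  parts <- lapply(cohort$sessions, function(s) {
    fixation_obs(segment_fixations(s$gaze$traj))
  })
  pooled <- do.call(rbind, parts)
  # sessions are independent chains: keep their segment ids disjoint
  offs <- cumsum(c(0L, vapply(parts, function(p) max(obs_seq(p)), integer(1L))))
  attr(pooled, "seq") <- unlist(lapply(seq_along(parts), function(i)
    obs_seq(parts[[i]]) + offs[i]))
  out <- lapply(mixture_factors, function(f) {
    nc <- max(1L, round(n_central * f))
    np <- max(1L, round(n_peripheral * f))
    init <- init_gaze_hmm(pooled, nc, np, dims = dims, seed = seed)
    hmm <- train_hmm(pooled, init)
    tbl <- do.call(rbind, lapply(seq_along(cohort$sessions), function(s) {
      analyze_session(cohort$sessions[[s]], hmm = hmm)
    }))
    pc <- pooled_correlation(tbl$transition_entropy, tbl$d_hr)
    tibble::tibble(factor = f, n_central = nc, n_peripheral = np,
                   r = pc$r, p = pc$p, n = pc$n)
  })
  do.call(rbind, out)
}
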