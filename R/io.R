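#' Pipeline configuration
#'
#' Central configuration record whose defaults reproduce the study
#' settings: heatmap kernel SD 10 px, 180 s analysis windows, per-scene HMM
#' mixture counts (courtyard-like scene 4 central / 9 peripheral, garden-like
#' scene 3 central / 12 peripheral), ROI GMM sizes chosen by BIC (13 and
#' 14 in the reference fits), device rates, and the options of the
#' inferential stages.
#'
#' @param sigma heatmap kernel SD, px.
#' @param window_s analysis window length, s.
#' @param hmm_components named list of `c(central, peripheral)` counts per scene.
#' @param mixture_sweep_factors factors for the robustness sweep.
#' @param ss_type ANOVA sums-of-squares type.
#' @param correlation_mode `"pooled"` windows or `"subject"` aggregation.
#' @param session a [session_config()].
#' @param seed root seed; all stage seeds are split from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sigma = 10, window_s = 180,
                            hmm_components = list(courtyard = c(4L, 9L),
                                                  garden = c(3L, 12L)),
                            mixture_sweep_factors = c(0.75, 1, 1.25),
                            ss_type = "III",
                            correlation_mode = "pooled",
                            session = session_config(), seed = 1L) {
  structure(list(sigma = sigma, window_s = window_s,
                 hmm_components = hmm_components,
                 mixture_sweep_factors = mixture_sweep_factors,
                 ss_type = ss_type, correlation_mode = correlation_mode,
                 session = unclass(session), seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path file path for the YAML round trip.
#' @param config a `pipeline_config`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$session <- do.call(session_config, raw$session)
  do.call(pipeline_config, raw)
}

#' Deterministic hash of a configuration
#'
#' 32-bit polynomial rolling hash over the YAML rendering; stamped into
#' every output file so results can be traced to the configuration that
#' produced them.
#'
#' @param config any serializable configuration object.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Write / read a gaze trajectory CSV
#'
#' Columns `t_s`, `x_px`, `y_px`, `valid`, with the image dimensions and an
#' optional config hash carried in `#`-prefixed header lines. Reading
#' validates the contract (columns present, strictly increasing time) and
#' reports the offending row on violation.
#'
#' @param traj a `gaze_trajectory`.
#' @param path file path.
#' @param config optional configuration stamped into the header.
#' @return `read_gaze_csv` returns a `gaze_trajectory`.
#' @export
write_gaze_csv <- function(traj, path, config = NULL) {
  stopifnot(inherits(traj, "gaze_trajectory"))
  dims <- image_dims(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# image_width=%d image_height=%d%s", dims[1L], dims[2L],
                     if (is.null(config)) "" else paste0(" config_hash=", config_hash(config))),
             con)
  write.csv(as.data.frame(traj), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("missing '# image_width=... image_height=...' header line")
  gw <- as.integer(sub(".*image_width=(\\d+).*", "\\1", header))
  gh <- as.integer(sub(".*image_height=(\\d+).*", "\\1", header))
  if (is.na(gw) || is.na(gh)) stop("malformed dimension header: ", header)
  df <- read.csv(path, comment.char = "#")
  need <- c("t_s", "x_px", "y_px", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!stats::complete.cases(df[, c("t_s", "valid")]))
  if (length(bad)) stop("malformed row at line ", bad[1L] + 2L)
  gaze_trajectory(df$t_s, df$x_px, df$y_px, as.logical(df$valid),
                  image_dims = c(gw, gh))
}

#' Write / read a single-channel physiology CSV
#'
#' One column `value`; the sampling rate and channel ride in a `#` header.
#'
#' @param rec a `physio_record`.
#' @param path file path.
#' @param config optional configuration stamped into the header.
#' @export
write_physio_csv <- function(rec, path, config = NULL) {
  stopifnot(inherits(rec, "physio_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%g channel=%s%s", rec$rate, rec$channel,
                     if (is.null(config)) "" else paste0(" config_hash=", config_hash(config))),
             con)
  writeLines("value", con)
  writeLines(format(rec$values, digits = 10, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_physio_csv
#' @export
read_physio_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("rate_hz=", header))
    stop("missing 'rate_hz=' header in ", path)
  rate <- as.numeric(sub(".*rate_hz=([0-9.eE+-]+).*", "\\1", header))
  channel <- sub(".*channel=(\\w+).*", "\\1", header)
  if (!channel %in% c("ECG", "GSR", "BVP")) channel <- "ECG"
  df <- read.csv(path, comment.char = "#")
  if (!"value" %in% names(df)) stop("missing 'value' column in ", path)
  physio_record(df$value, rate, channel)
}

#' Serialize / restore a gaze HMM as JSON
#'
#' Schema: states with mixture weights, means, covariances (row-major),
#' transition matrix `A` and initial probabilities `p`.
#'
#' @param hmm a `gaze_hmm`.
#' @param path file path.
#' @export
write_hmm_json <- function(hmm, path) {
  stopifnot(inherits(hmm, "gaze_hmm"))
  obj <- list(
    n_states = 2L,
    A = hmm$A, p = hmm$p,
    states = lapply(hmm$emissions, function(e) {
      list(weights = e$weights, means = e$means,
           covariances = lapply(seq_len(n_components(e)),
                                function(m) e$covs[, , m]))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_mat <- function(rows) do.call(rbind, lapply(rows, unlist))
  emissions <- lapply(obj$states, function(s) {
    w <- unlist(s$weights)
    M <- length(w)
    covs <- array(0, c(2L, 2L, M))
    for (m in seq_len(M)) covs[, , m] <- as_mat(s$covariances[[m]])
    gaussian_mixture(w, as_mat(s$means), covs)
  })
  gaze_hmm(as_mat(obj$A), unlist(obj$p), emissions)
}

#' Write a ground-truth sidecar for a simulated session
#'
#' JSON record of the generator's hidden parameters (per-window transition
#' matrices and entropies, true beat times, RMSSD / SCL settings, coupling
#' slope) used by recovery tests.
#'
#' @param session a `session` from [simulate_session()].
#' @param path file path.
#' @export
write_ground_truth_json <- function(session, path) {
  stopifnot(inherits(session, "session"))
  jsonlite::write_json(
    list(windows = session$windows, truth = session$truth,
         beat_times = session$beat_times),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
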