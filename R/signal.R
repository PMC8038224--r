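# EMG amplitude estimation, tap-marker detection and stream
# synchronization onto the common 50 Hz grid.

#' EMG envelope parameters
#'
#' @param smoothing_cutoff low-pass cutoff for the rectified signal, Hz;
#'   must lie in (0, 25) (Nyquist of the 50 Hz target grid).  3 Hz is a
#'   conventional envelope bandwidth for trunk-load estimation.
#' @param rectification only "full_wave" is defined.
#' @return object of class `envelope_params`.
#' @export
envelope_params <- function(smoothing_cutoff = 3,
                            rectification = "full_wave") {
  rectification <- match.arg(rectification, "full_wave")
  if (smoothing_cutoff <= 0 || smoothing_cutoff >= SAMPLE_RATE / 2)
    stop("smoothing_cutoff must lie in (0, 25) Hz")
  structure(list(smoothing_cutoff = smoothing_cutoff,
                 rectification = rectification,
                 target_rate = SAMPLE_RATE),
            class = "envelope_params")
}

#' EMG amplitude (envelope) estimation
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass (applied forward-backward), then linear interpolation onto the
#' 50 Hz session grid.  The envelope is clipped at zero (the zero-phase
#' filter can undershoot slightly at sharp transients).
#'
#' @param raw an [emg_stream()] with a raw track.
#' @param params an [envelope_params()].
#' @return the stream with `t_env` and `envelope` filled in.
#' @export
emg_amplitude <- function(raw, params = envelope_params()) {
  stopifnot(inherits(raw, "emg_stream"))
  rate <- emg_raw_rate(raw)
  if (rate < 4 * params$smoothing_cutoff)
    stop(sprintf(
      "raw EMG rate %.0f Hz too low for a %.1f Hz envelope (need >= 4x)",
      rate, params$smoothing_cutoff))
  rect <- abs(raw$raw)
  bf <- signal::butter(2, params$smoothing_cutoff / (rate / 2), type = "low")
  env <- as.numeric(signal::filtfilt(bf, rect))
  t0 <- ceiling(raw$t_raw[1] / SAMPLE_DT - 1e-9) * SAMPLE_DT
  t1 <- floor(raw$t_raw[length(raw$t_raw)] / SAMPLE_DT + 1e-9) * SAMPLE_DT
  t_env <- seq(t0, t1, by = SAMPLE_DT)
  e <- stats::approx(raw$t_raw, env, xout = t_env, rule = 2)$y
  raw$t_env <- t_env
  raw$envelope <- pmax(0, e)
  validate_emg_stream(raw)
  raw
}

#' Detect the synchronization tap marker in a stream
#'
#' Finds the highest transient in the pre-trial window of a stream and
#' rates it against the next-largest candidate at least 0.1 s away.  The
#' marker is the transient's peak time; `confidence` is the amplitude ratio
#' to the runner-up and must exceed 1 for an accepted detection (the peak
#' must also rise well above the noise floor).
#'
#' @param stream an [emg_stream()] (raw track), an [immu_stream()]
#'   (accelerometer transient) or a numeric vector (then supply `t`).
#' @param t sample times when `stream` is a bare numeric vector.
#' @param window length of the pre-trial search window from the first
#'   sample, s.
#' @return list with `time` (s, on the stream's own clock) and
#'   `confidence`.
#' @export
detect_tap_marker <- function(stream, t = NULL, window = 1.5) {
  if (inherits(stream, "emg_stream")) {
    x <- stream$raw; tt <- stream$t_raw
  } else if (inherits(stream, "immu_stream")) {
    dev <- sweep(stream$linacc, 2, apply(stream$linacc, 2, stats::median))
    x <- sqrt(rowSums(dev^2)); tt <- stream$t
  } else {
    x <- as.numeric(stream); tt <- t
    if (is.null(tt)) stop("supply sample times 't' for a numeric stream")
  }
  keep <- tt <= tt[1] + window
  x <- x[keep]; tt <- tt[keep]
  d <- abs(x - stats::median(x))
  noise <- stats::mad(x)
  i1 <- which.max(d)
  p1 <- d[i1]
  if (p1 <= 0 || (noise > 0 && p1 < 5 * noise))
    stop("no synchronization transient found in the pre-trial window")
  away <- abs(tt - tt[i1]) > 0.1
  p2 <- if (any(away)) max(d[away]) else 0
  conf <- if (p2 > 0) p1 / p2 else Inf
  if (conf <= 1)
    stop("ambiguous synchronization transient (confidence <= 1)")
  list(time = tt[i1], confidence = conf)
}

#' Synchronize EMG streams onto the inertial master clock
#'
#' Detects the tap markers injected before the start of the measurement in
#' the sacrum accelerometer (master clock) and the EMG channels, estimates
#' the EMG clock offset as the difference of the marker times (median over
#' the EMG channels with a confident marker), and shifts every EMG stream of
#' every trial onto the inertial clock.  Envelopes, if already computed, are
#' re-gridded onto the 50 Hz master grid after shifting.
#'
#' @param ses a [session()] whose first trials contain the tap markers.
#' @param window pre-trial search window, s.
#' @return the session with corrected EMG time stamps and a `sync_result`
#'   in `$sync` (fields `offset` = EMG clock minus inertial clock in s,
#'   `marker_times`, `confidence`).
#' @export
synchronize <- function(ses, window = 1.5) {
  stopifnot(inherits(ses, "session"))
  res <- NULL
  for (tr in ses$trials) {
    res <- tryCatch({
      im <- detect_tap_marker(tr$immu$sacrum, window = window)
      markers <- list(); conf <- c()
      for (ch in names(tr$emg)) {
        m <- tryCatch(detect_tap_marker(tr$emg[[ch]], window = window),
                      error = function(e) NULL)
        if (!is.null(m)) { markers[[ch]] <- m$time; conf[ch] <- m$confidence }
      }
      if (!length(markers)) stop("no EMG marker")
      list(trial = tr$id, immu_time = im$time,
           emg_times = unlist(markers),
           offset = stats::median(unlist(markers)) - im$time,
           confidence = c(sacrum = im$confidence, conf))
    }, error = function(e) NULL)
    if (!is.null(res)) break
  }
  if (is.null(res))
    stop("synchronization failed: no trial with detectable tap markers")

  ses$trials <- lapply(ses$trials, function(tr) {
    tr$emg <- lapply(tr$emg, function(es) {
      es$t_raw <- es$t_raw - res$offset
      if (!is.null(es$envelope)) {
        shifted <- es$t_env - res$offset
        t0 <- ceiling(shifted[1] / SAMPLE_DT - 1e-9) * SAMPLE_DT
        t1 <- floor(shifted[length(shifted)] / SAMPLE_DT + 1e-9) * SAMPLE_DT
        grid <- seq(t0, t1, by = SAMPLE_DT)
        es$envelope <- pmax(0, stats::approx(shifted, es$envelope,
                                             xout = grid, rule = 2)$y)
        es$t_env <- grid
      }
      es
    })
    tr
  })
  ses$sync <- structure(
    list(offset = res$offset,
         marker_times = c(sacrum = res$immu_time, res$emg_times),
         confidence = res$confidence, source_trial = res$trial),
    class = "sync_result")
  ses
}

# compute envelopes for every EMG stream of every trial
envelope_session <- function(ses, params = envelope_params()) {
  ses$trials <- lapply(ses$trials, function(tr) {
    tr$emg <- lapply(tr$emg, emg_amplitude, params = params)
    tr
  })
  ses
}
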