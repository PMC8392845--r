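#' Bandpass-filter, zero-center and rectify a raw sEMG trace
#'
#' Applies a fourth-order Butterworth 20-450 Hz bandpass (zero-phase, via
#' forward-backward filtering so the envelope stays time-aligned with the
#' goniometer trace), removes the residual mean and full-wave rectifies.
#'
#' @param raw Numeric vector, one raw sEMG channel.
#' @param fs Sampling rate in Hz; must exceed 900 so the upper passband
#'   edge stays below Nyquist.
#' @param low,high Passband edges in Hz.
#' @param order Butterworth design order.
#' @return Non-negative numeric vector of the same length.
#' @export
filter_and_rectify <- function(raw, fs, low = 20, high = 450, order = 4) {
  if (fs <= 2 * high) {
    stop("sampling-rate error: fs = ", fs, " Hz places the ", high,
         " Hz passband edge at or above Nyquist")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, raw)
  abs(y - mean(y))
}

#' Per-channel session maxima of rectified sEMG
#'
#' Amplitude normalization divides each muscle by its maximum over all of
#' the subject's movements; this computes those maxima across a list of
#' rectified channel matrices (one per recording of the same subject).
#'
#' @param rectified_list List of non-negative channels x samples matrices.
#' @return Numeric vector of per-channel maxima.
#' @export
session_maxima <- function(rectified_list) {
  if (is.matrix(rectified_list)) rectified_list <- list(rectified_list)
  apply(do.call(cbind, rectified_list), 1, max)
}

#' Normalize rectified sEMG and extract the RMS envelope
#'
#' Each channel is divided by its session maximum, then smoothed with a
#' centered 100 ms moving root-mean-square window (shrink-to-valid at the
#' edges), yielding the non-negative envelope matrix that is factorized
#' downstream.
#'
#' @param rectified Non-negative channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param window_ms RMS window length in milliseconds.
#' @param session_max Per-channel maxima over the subject's whole session
#'   (see [session_maxima()]); must be strictly positive.
#' @return Envelope matrix (channels x samples) with entries in [0, 1] and
#'   attribute `fs`.
#' @export
normalize_and_envelope <- function(rectified, fs, window_ms = 100,
                                   session_max) {
  rectified <- as.matrix(rectified)
  m <- nrow(rectified)
  if (length(session_max) != m) {
    stop("session_max must have one entry per channel")
  }
  bad <- which(session_max <= 0)
  if (length(bad)) {
    nms <- rownames(rectified)
    lab <- if (is.null(nms)) as.character(bad) else nms[bad]
    stop("degenerate-channel error: zero session maximum for channel(s) ",
         paste(lab, collapse = ", "))
  }
  width <- max(1L, round(window_ms * fs / 1000))
  env <- t(vapply(seq_len(m), function(i) {
    moving_rms(rectified[i, ] / session_max[i], width)
  }, numeric(ncol(rectified))))
  dimnames(env) <- dimnames(rectified)
  attr(env, "fs") <- fs
  env
}

#' Segment a recording into motion repetitions from the knee-angle trace
#'
#' The angle trace is smoothed by a centered moving average and angular
#' speed taken as its central first difference. For `STD`/`ST` each
#' repetition is a bell-shaped excursion found by prominence-based peak
#' detection; the repetition starts at the first sample whose absolute
#' speed reaches 10% of the initiating phase's maximum speed and ends at
#' the first sample after the terminal-phase speed peak where the absolute
#' speed drops below 10% of that phase's maximum. For `Gait`, cycle
#' boundaries are the first local angle minimum after each angle maximum
#' (the start of the support phase); segments span consecutive boundaries.
#'
#' @param angle Knee angle in degrees, one sample per time step.
#' @param fs Sampling rate in Hz.
#' @param motion `"STD"`, `"ST"` or `"Gait"`.
#' @param smooth_ms Moving-average window for the angle trace, ms.
#' @param speed_threshold_frac Fraction of the per-phase maximum speed
#'   defining the start/end crossings.
#' @param min_prominence_frac Minimum peak prominence as a fraction of the
#'   angle range.
#' @param min_separation_s Minimum separation between repetition peaks, s.
#' @return Data frame with 0-based half-open columns `start`, `end` and a
#'   `motion` column; zero rows (with a warning) when no repetition is
#'   found.
#' @export
segment_motion <- function(angle, fs, motion, smooth_ms = 100,
                           speed_threshold_frac = 0.10,
                           min_prominence_frac = 0.20,
                           min_separation_s = 1) {
  motion <- match.arg(motion, c("STD", "ST", "Gait"))
  if (length(angle) < fs) stop("angle trace shorter than 1 s")
  s <- moving_average(angle, max(1L, round(smooth_ms * fs / 1000)))
  n <- length(s)
  v <- c(s[2] - s[1], (s[3:n] - s[1:(n - 2)]) / 2, s[n] - s[n - 1]) * fs
  rng <- diff(range(s))
  empty <- data.frame(start = integer(0), end = integer(0),
                      motion = character(0))
  if (rng < .Machine$double.eps^0.5) {
    warning("no repetitions detected: flat angle trace")
    return(empty)
  }
  peaks <- find_peaks(s, prominence = min_prominence_frac * rng,
                      min_dist = round(min_separation_s * fs))
  if (!length(peaks)) {
    warning("no repetitions detected")
    return(empty)
  }
  if (motion == "Gait") {
    bounds <- integer(0)
    for (p in peaks) {
      mins <- find_peaks(-s[p:n], prominence = min_prominence_frac * rng / 2,
                         min_dist = 1L)
      if (length(mins)) bounds <- c(bounds, p + mins[1] - 1L)
    }
    bounds <- sort(unique(bounds))
    if (length(bounds) < 2) {
      warning("no full gait cycles detected")
      return(empty)
    }
    return(data.frame(start = bounds[-length(bounds)] - 1L,
                      end = bounds[-1] - 1L, motion = motion))
  }
  # STD / ST: regions around each bell, split at midpoints between peaks
  lims <- c(1L, floor((peaks[-length(peaks)] + peaks[-1]) / 2), n)
  segs <- lapply(seq_along(peaks), function(i) {
    lo <- lims[i]
    hi <- lims[i + 1]
    p <- peaks[i]
    init <- abs(v[lo:p])
    ipk <- lo + which.max(init) - 1L
    thr1 <- speed_threshold_frac * max(init)
    # first sample of the contiguous run of >= 10%-speed samples leading
    # into the initiating speed peak (scanning back from the peak keeps
    # sensor noise during the preceding rest from triggering early)
    below <- which(abs(v[lo:ipk]) < thr1)
    start <- if (length(below)) lo + below[length(below)] else lo
    term <- abs(v[p:hi])
    tpk <- p + which.max(term) - 1L
    thr2 <- speed_threshold_frac * max(term)
    after <- which(abs(v[tpk:hi]) < thr2)
    end <- if (length(after)) tpk + after[1] - 1L else hi
    c(start, end)
  })
  segs <- do.call(rbind, segs)
  data.frame(start = segs[, 1] - 1L, end = segs[, 2], motion = motion)
}

#' Resample a segment's envelope to a fixed number of samples
#'
#' Linear interpolation of each channel onto a uniform grid from the first
#' to the last sample (the common 100-point time base used before
#' per-segment factorization).
#'
#' @param envelope Channels x samples matrix with at least 2 samples.
#' @param n_out Output sample count.
#' @return Channels x `n_out` matrix.
#' @export
resample_segment <- function(envelope, n_out = 100) {
  envelope <- as.matrix(envelope)
  L <- ncol(envelope)
  if (L < 2) stop("degenerate-segment error: fewer than 2 samples")
  xout <- seq(1, L, length.out = n_out)
  out <- t(apply(envelope, 1, function(row) {
    stats::approx(seq_len(L), row, xout = xout, method = "linear")$y
  }))
  rownames(out) <- rownames(envelope)
  out
}

#' Preprocess a whole cohort of recordings
#'
#' Rectifies every channel, computes per-subject session maxima, extracts
#' normalized RMS envelopes and segments each recording by its angle
#' trace.
#'
#' @param recordings List of [emg_recording()] objects.
#' @param window_ms Envelope RMS window, ms.
#' @param ... Passed to [segment_motion()].
#' @return List (one element per recording) of lists with `recording`,
#'   `envelope` and `segments`.
#' @export
preprocess_cohort <- function(recordings, window_ms = 100, ...) {
  rect <- lapply(recordings, function(rec) {
    t(apply(rec$semg, 1, filter_and_rectify, fs = rec$fs))
  })
  subj <- vapply(recordings, function(r) r$subject_id, "")
  smax <- lapply(unique(subj), function(sid) {
    session_maxima(rect[subj == sid])
  })
  names(smax) <- unique(subj)
  lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    env <- normalize_and_envelope(rect[[i]], rec$fs, window_ms,
                                  smax[[rec$subject_id]])
    segs <- segment_motion(rec$angle, rec$fs, rec$motion, ...)
    list(recording = rec, envelope = env, segments = segs)
  })
}

#' Cut and resample the segment envelopes of a preprocessed recording
#'
#' @param processed One element of [preprocess_cohort()]'s result.
#' @param n_out Samples per resampled segment.
#' @return List of channels x `n_out` matrices, one per segment.
#' @export
segment_envelopes <- function(processed, n_out = 100) {
  segs <- processed$segments
  lapply(seq_len(nrow(segs)), function(i) {
    sl <- processed$envelope[, (segs$start[i] + 1L):segs$end[i],
                             drop = FALSE]
    resample_segment(sl, n_out)
  })
}
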