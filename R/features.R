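#' Slide a fixed-length window over a continuous envelope
#'
#' Windows of `window` samples whose starts step by `window - overlap`
#' samples (256 and 64 by default, i.e. a 192-sample step with 64 shared
#' samples between neighbours); the final partial window is discarded.
#'
#' @param envelope Channels x samples matrix.
#' @param window Window length in samples.
#' @param overlap Shared samples between consecutive windows.
#' @return List of channels x `window` matrices, each with a 0-based
#'   `start` attribute; empty (with a warning) when the envelope is
#'   shorter than one window.
#' @export
window_stream <- function(envelope, window = 256, overlap = 64) {
  envelope <- as.matrix(envelope)
  n <- ncol(envelope)
  if (n < window) {
    warning("envelope shorter than one window; returning no windows")
    return(list())
  }
  step <- as.integer(window - overlap)
  starts <- seq.int(0L, as.integer(n - window), by = step)
  lapply(starts, function(s) {
    w <- envelope[, (s + 1L):(s + window), drop = FALSE]
    attr(w, "start") <- s
    w
  })
}

#' Reorder synergies by activation ratio
#'
#' The activation ratio of synergy `i` is `RMS(h_i) / sum_j RMS(h_j)`.
#' Columns of `W` and rows of `H` move together and are sorted by ratio,
#' largest first (stable on ties), removing the arbitrary ordering left by
#' random NMF initialization.
#'
#' @param W Synergy pattern matrix (m x k).
#' @param H Activation coefficient matrix (k x n), not all zero.
#' @return List with reordered `W`, `H` and the sorted ratios `r`
#'   (summing to 1).
#' @export
reorder_by_activation_ratio <- function(W, H) {
  W <- as.matrix(W)
  H <- as.matrix(H)
  rms <- sqrt(rowMeans(H^2))
  if (sum(rms) == 0) stop("undefined-ratio error: H is all zero")
  r <- rms / sum(rms)
  ord <- order(-r)
  list(W = W[, ord, drop = FALSE], H = H[ord, , drop = FALSE], r = r[ord])
}

# Fourth-order AR coefficients of a series, in the convention
# h_t = -sum_i a_i h_{t-i} + e_t (Burg estimator). Degenerate series
# (constant, or a failed fit) yield zeros with a warning.
ar4_coefficients <- function(h) {
  if (stats::sd(h) == 0) {
    warning("constant activation row: AR coefficients set to 0")
    return(rep(0, 4))
  }
  fit <- tryCatch(
    stats::ar(h, aic = FALSE, order.max = 4, method = "burg"),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) < 4) {
    warning("degenerate AR fit: coefficients set to 0")
    return(rep(0, 4))
  }
  -fit$ar
}

#' Extract classification features from a reordered factorization
#'
#' The coarse set is the flattened synergy pattern matrix in synergy-major
#' order (`W11..W1m, ..., Wk1..Wkm`, where `Wij` is the weight of muscle
#' `j` in synergy `i`). The fine set appends, per activation row `i`, the
#' time-domain features `rms` (root mean square), `AR2..AR5` (the four
#' coefficients of a fourth-order autoregressive model, Burg-fitted),
#' `IQR` (interquartile range, type-7 quartiles), `WL` (waveform length,
#' the summed absolute first difference) and `MAV` (mean absolute value) —
#' 8 per synergy, giving 24 features for k = 2 and 36 for k = 3.
#'
#' @param W,H Reordered factor matrices (see
#'   [reorder_by_activation_ratio()]).
#' @param feature_set `"fine"` or `"coarse"`.
#' @return Named numeric feature vector.
#' @export
extract_features <- function(W, H, feature_set = c("fine", "coarse")) {
  feature_set <- match.arg(feature_set)
  W <- as.matrix(W)
  H <- as.matrix(H)
  k <- ncol(W)
  m <- nrow(W)
  vals <- as.vector(W)
  names(vals) <- paste0("W", rep(seq_len(k), each = m),
                        rep(seq_len(m), k))
  if (feature_set == "coarse") return(vals)
  for (i in seq_len(k)) {
    h <- H[i, ]
    fi <- c(sqrt(mean(h^2)),
            ar4_coefficients(h),
            diff(stats::quantile(h, c(0.25, 0.75), names = FALSE,
                                 type = 7)),
            sum(abs(diff(h))),
            mean(abs(h)))
    names(fi) <- paste0(c("rms", "AR2", "AR3", "AR4", "AR5", "IQR",
                          "WL", "MAV"), i)
    vals <- c(vals, fi)
  }
  vals
}

#' Per-window synergy features for a preprocessed cohort
#'
#' Slides windows over each recording's envelope (restricted to the
#' detected motion segments by default, so rest periods do not contribute
#' windows), factorizes each window at synergy number `k`, reorders by
#' activation ratio and extracts features, together with the window's
#' labels.
#'
#' @param processed Result of [preprocess_cohort()].
#' @param k Synergy number used for every window.
#' @param feature_set `"fine"` or `"coarse"`.
#' @param window,overlap Windowing controls (see [window_stream()]).
#' @param windows_from `"segments"` (window each detected motion segment)
#'   or `"recording"` (window the full envelope, rests included).
#' @param n_random_restarts,max_iter,tol NMF controls per window.
#' @param seed Seed for the per-window NMF restarts.
#' @return Data frame: one row per window with feature columns plus
#'   `motion`, `group`, `subject_id` labels.
#' @export
cohort_window_features <- function(processed, k,
                                   feature_set = c("fine", "coarse"),
                                   window = 256, overlap = 64,
                                   windows_from = c("segments",
                                                    "recording"),
                                   n_random_restarts = 20,
                                   max_iter = 1000, tol = 1e-6,
                                   seed = NULL) {
  feature_set <- match.arg(feature_set)
  windows_from <- match.arg(windows_from)
  rows <- list()
  with_seed(seed, {
    for (p in processed) {
      envs <- if (windows_from == "segments") {
        segs <- p$segments
        lapply(seq_len(nrow(segs)), function(i) {
          p$envelope[, (segs$start[i] + 1L):segs$end[i], drop = FALSE]
        })
      } else {
        list(p$envelope)
      }
      for (env in envs) {
        for (win in suppressWarnings(window_stream(env, window, overlap))) {
          dec <- nmf_decompose(win, k,
                               n_random_restarts = n_random_restarts,
                               max_iter = max_iter, tol = tol)
          ro <- reorder_by_activation_ratio(dec$W, dec$H)
          feats <- extract_features(ro$W, ro$H, feature_set)
          rows[[length(rows) + 1L]] <- c(
            as.list(feats),
            list(motion = p$recording$motion,
                 group = p$recording$group,
                 subject_id = p$recording$subject_id))
        }
      }
    }
  })
  if (!length(rows)) {
    stop("no windows produced; are the recordings long enough?")
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
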