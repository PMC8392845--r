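#' Specification for a synthetic sEMG cohort
#'
#' Defines the conditions of a simulated study cohort: planted synergy
#' structure per motion, repetition counts, noise levels and the size of
#' the between-group synergy difference. Defaults mirror the protocol of
#' the source data: four thigh muscles sampled at 1000 Hz, movements built
#' from 2 s flexion, 2 s hold and 2 s extension phases with 3 s rests,
#' gait cycles of 1.32 s, and two synergies underlying the isolated
#' flexion/extension motions versus three for gait.
#'
#' @param m Number of sEMG channels.
#' @param k_true Planted synergy count per motion; a single value or a
#'   named vector over `STD`, `ST`, `Gait`.
#' @param n_subjects Subjects per group (CG and SG each).
#' @param reps Movements (STD/ST repetitions or gait cycles) per recording.
#' @param fs Sampling rate in Hz (must exceed 900 so the 20-450 Hz carrier
#'   band fits below Nyquist).
#' @param noise_sd Envelope noise scale as a fraction of the peak envelope.
#' @param group_shift Magnitude of the perturbation applied to the SG
#'   group's planted synergy pattern matrix (0 = identical groups).
#' @param gait_cycle_s Planted gait cycle duration in seconds.
#' @param seed Root seed; every recording derives its own stream from it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(m = 4, k_true = c(STD = 2, ST = 2, Gait = 3),
                       n_subjects = 5, reps = 5, fs = 1000,
                       noise_sd = 0.05, group_shift = 0.4,
                       gait_cycle_s = 1.32, seed = 1) {
  motions <- c("STD", "ST", "Gait")
  if (length(k_true) == 1L) k_true <- stats::setNames(rep(k_true, 3), motions)
  if (is.null(names(k_true))) names(k_true) <- motions
  if (any(k_true < 1) || any(k_true > m)) {
    stop("specification error: k_true must lie in 1..m for every motion")
  }
  if (noise_sd < 0) stop("specification error: noise_sd must be >= 0")
  if (reps < 1) stop("specification error: reps must be >= 1")
  if (fs <= 900) stop("specification error: fs must exceed 900 Hz")
  structure(
    list(m = m, k_true = k_true[motions], n_subjects = n_subjects,
         reps = reps, fs = fs, noise_sd = noise_sd,
         group_shift = group_shift, gait_cycle_s = gait_cycle_s,
         seed = seed),
    class = "synth_spec")
}

# Deterministic planted synergy pattern matrix: Gaussian bumps across
# channels, staggered per synergy with a motion-specific phase so that
# different motions recruit visibly different patterns. Columns unit-norm.
planted_w <- function(m, k, motion) {
  phase <- c(STD = 0, ST = 1 / 3, Gait = 2 / 3)[[motion]]
  W <- matrix(0, m, k)
  for (j in seq_len(k)) {
    mu <- 1 + (((j - 1) / k + phase) %% 1) * (m - 1)
    W[, j] <- 0.02 + exp(-0.5 * ((seq_len(m) - mu) / (m / 8))^2)
  }
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

# Deterministic, motion-specific perturbation direction for the SG group.
planted_shift_dir <- function(m, k, motion) {
  ph <- c(STD = 0.1, ST = 0.45, Gait = 0.8)[[motion]]
  D <- matrix(0, m, k)
  for (j in seq_len(k)) {
    D[, j] <- sin(2 * pi * (seq_len(m) / m + ph + j / (k + 1)))
    D[, j] <- D[, j] / sqrt(sum(D[, j]^2))
  }
  D
}

# Planted synergy pattern for one group: CG uses the base pattern, SG the
# base pattern shifted along a fixed direction, clipped non-negative and
# renormalized.
planted_group_w <- function(spec, motion, group) {
  k <- spec$k_true[[motion]]
  W <- planted_w(spec$m, k, motion)
  if (group == "SG" && spec$group_shift > 0) {
    W <- pmax(W + spec$group_shift * planted_shift_dir(spec$m, k, motion),
              0.01)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  }
  W
}

# Activation bumps for one movement of length L samples: synergy j peaks at
# phase (j - 1/2)/k of the movement.
movement_activation <- function(k, L) {
  H <- matrix(0, k, L)
  t <- seq_len(L)
  for (j in seq_len(k)) {
    H[j, ] <- exp(-0.5 * ((t - (j - 0.5) / k * L) / (L / (4 * k)))^2)
  }
  H
}

# Band-limited (20-450 Hz) unit-variance carrier noise.
carrier_noise <- function(n, fs) {
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate one synthetic recording with known ground truth
#'
#' Builds a raw multi-channel sEMG recording whose rectified-and-smoothed
#' envelope approximates a planted factorization `W_true %*% H_true`: each
#' channel is band-limited carrier noise amplitude-modulated by its planted
#' envelope row (plus a small sensor noise floor and optional envelope
#' noise). The knee-angle trace is a train of raised-cosine bells for
#' STD/ST (2 s rise, 2 s hold, 2 s fall, 3 s rests) or a cyclic trace with
#' one clear minimum per cycle for Gait.
#'
#' @param spec A [synth_spec()].
#' @param subject_id Subject identifier.
#' @param group `"CG"` or `"SG"`; SG uses the shifted synergy pattern.
#' @param motion `"STD"`, `"ST"` or `"Gait"`.
#' @return A list with elements `recording` (an [emg_recording()]) and
#'   `truth` (list with `W`, full-length `H`, and a `movements` data frame
#'   of 0-based half-open planted movement spans).
#' @export
generate_recording <- function(spec, subject_id, group, motion) {
  group <- match.arg(group, c("CG", "SG"))
  motion <- match.arg(motion, c("STD", "ST", "Gait"))
  fs <- spec$fs
  k <- spec$k_true[[motion]]
  W <- planted_group_w(spec, motion, group)
  with_seed(derive_seed(spec$seed, subject_id, motion), {
    if (motion == "Gait") {
      lead <- round(1 * fs)
      cyc <- round(spec$gait_cycle_s * fs)
      total <- lead + spec$reps * cyc + lead
      # standing rest sits at slight flexion (15 deg), above the swing-phase
      # minimum, so the last cycle still ends in a detectable angle minimum
      angle <- rep(15, total)
      starts <- lead + (seq_len(spec$reps) - 1L) * cyc
      u <- (seq_len(cyc) - 1) / cyc
      bell <- 5 + 55 * 0.5 * (1 - cos(2 * pi * u))
      H <- matrix(0, k, total)
      for (s in starts) {
        angle[s + seq_len(cyc)] <- bell
        H[, s + seq_len(cyc)] <- movement_activation(k, cyc)
      }
      mv <- data.frame(start = starts, end = starts + cyc)
    } else {
      lead <- round(2 * fs)
      move <- round(6 * fs)
      rest <- round(3 * fs)
      total <- lead + spec$reps * move + (spec$reps - 1L) * rest + lead
      angle <- rep(5, total)
      t2 <- seq_len(round(2 * fs))
      rise <- 5 + 60 * 0.5 * (1 - cos(pi * t2 / length(t2)))
      bell <- c(rise, rep(65, round(2 * fs)),
                rev(rise)[seq_len(move - 2 * length(t2))])
      starts <- lead + (seq_len(spec$reps) - 1L) * (move + rest)
      H <- matrix(0, k, total)
      for (s in starts) {
        angle[s + seq_len(move)] <- bell[seq_len(move)]
        H[, s + seq_len(move)] <- movement_activation(k, move)
      }
      mv <- data.frame(start = starts, end = starts + move)
    }
    angle <- angle + stats::rnorm(total, sd = 0.2)
    E <- W %*% H
    if (spec$noise_sd > 0) {
      E <- pmax(E + spec$noise_sd * max(E) *
                  matrix(stats::rnorm(length(E)), nrow(E)), 0)
    }
    floor_amp <- 0.001 * max(E)
    semg <- t(vapply(seq_len(spec$m), function(i) {
      (E[i, ] + floor_amp) * carrier_noise(total, fs)
    }, numeric(total)))
    ch <- if (spec$m == 4) c("RF", "FB", "VM", "SEM") else
      paste0("ch", seq_len(spec$m))
    rec <- emg_recording(semg, angle, fs = fs, subject_id = subject_id,
                         group = group, motion = motion,
                         channel_names = ch)
    list(recording = rec,
         truth = list(W = W, H = H, movements = mv))
  })
}

#' Generate a full synthetic cohort
#'
#' One recording per subject and motion for both groups.
#'
#' @param spec A [synth_spec()].
#' @return Named list of `generate_recording()` results, names
#'   `"<subject>_<motion>"`.
#' @export
generate_cohort <- function(spec) {
  subjects <- c(sprintf("CG%02d", seq_len(spec$n_subjects)),
                sprintf("SG%02d", seq_len(spec$n_subjects)))
  groups <- rep(c("CG", "SG"), each = spec$n_subjects)
  out <- list()
  for (i in seq_along(subjects)) {
    for (motion in c("STD", "ST", "Gait")) {
      out[[paste0(subjects[i], "_", motion)]] <-
        generate_recording(spec, subjects[i], groups[i], motion)
    }
  }
  out
}

#' Write a synthetic cohort to disk in the package's text formats
#'
#' Writes each recording as tab-delimited text plus a `manifest.csv`
#' readable by [load_cohort()].
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(cohort), function(nm) {
    rec <- cohort[[nm]]$recording
    fname <- paste0(nm, ".txt")
    write_recording(rec, file.path(dir, fname))
    data.frame(path = fname, subject_id = rec$subject_id,
               group = rec$group, motion = rec$motion)
  })
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

#' Column layout of recordings written by [write_cohort()]
#'
#' @param m Number of sEMG channels.
#' @return Named 0-based column index vector for [read_recording()].
#' @export
cohort_layout <- function(m = 4) {
  ch <- if (m == 4) c("RF", "FB", "VM", "SEM") else paste0("ch", seq_len(m))
  stats::setNames(seq_len(m + 1L) - 1L, c(ch, "angle"))
}
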