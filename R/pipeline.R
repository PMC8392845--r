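#' Per-motion synergy analysis of a preprocessed cohort
#'
#' For every motion: pools the resampled segment envelopes of all
#' recordings, selects the synergy number by the mean-VAF > 0.85 rule,
#' decomposes every segment at the selected number, and builds one
#' representative synergy (pattern + activation) per subject with the
#' 3-sigma similarity outlier rule.
#'
#' @param processed Result of [preprocess_cohort()].
#' @param vaf_threshold Mean-VAF threshold for the synergy number.
#' @param n_out Samples per resampled segment.
#' @param seed Seed for the NMF restarts.
#' @param ... Passed to [nmf_decompose()].
#' @return List with per-motion `k`, `mean_vaf` curves, a data frame
#'   `gait_durations` (seconds per gait segment), `n_outliers`,
#'   `n_matrices`, and `representatives`, a list of per subject x motion
#'   entries (`subject_id`, `group`, `motion`, `W`, `H`).
#' @export
motion_synergy_analysis <- function(processed, vaf_threshold = 0.85,
                                    n_out = 100, seed = NULL, ...) {
  motions <- unique(vapply(processed, function(p) p$recording$motion, ""))
  seg_env <- lapply(processed, segment_envelopes, n_out = n_out)
  k_sel <- list()
  vaf_curves <- list()
  reps <- list()
  n_out_total <- 0L
  n_mat_total <- 0L
  gait_dur <- numeric(0)
  with_seed(seed, {
    for (motion in motions) {
      in_motion <- vapply(processed,
                          function(p) p$recording$motion == motion, TRUE)
      segs <- unlist(seg_env[in_motion], recursive = FALSE)
      k <- select_synergy_number(segs, vaf_threshold = vaf_threshold, ...)
      k_sel[[motion]] <- as.integer(k)
      vaf_curves[[motion]] <- attr(k, "mean_vaf")
      for (i in which(in_motion)) {
        p <- processed[[i]]
        if (motion == "Gait") {
          gait_dur <- c(gait_dur,
                        (p$segments$end - p$segments$start) /
                          p$recording$fs)
        }
        segs_i <- seg_env[[i]]
        if (length(segs_i) < 2) next
        Ws <- lapply(segs_i, function(A) {
          nmf_decompose(A, k_sel[[motion]], ...)$W
        })
        rep_i <- build_representative(Ws, segs_i)
        n_out_total <- n_out_total + length(rep_i$outliers)
        n_mat_total <- n_mat_total + length(Ws)
        reps[[length(reps) + 1L]] <- list(
          subject_id = p$recording$subject_id,
          group = p$recording$group, motion = motion,
          W = rep_i$W, H = rep_i$H)
      }
    }
  })
  list(k = k_sel, mean_vaf = vaf_curves,
       gait_durations = gait_dur,
       n_outliers = n_out_total, n_matrices = n_mat_total,
       representatives = reps)
}

#' Intra/inter-group similarity tables from representative synergies
#'
#' For each motion, computes the intra-similarity of the CG and SG groups
#' (and the combined group) and the CG-SG inter-similarity, for both the
#' synergy pattern matrices and the activation coefficient matrices.
#'
#' @param representatives The `representatives` element of
#'   [motion_synergy_analysis()]'s result.
#' @return Data frame with columns `motion`, `matrix` (`W` or `H`),
#'   `measure` (`intra_CG`, `intra_SG`, `intra_combined`, `inter_CG_SG`)
#'   and `similarity`.
#' @export
similarity_tables <- function(representatives) {
  motions <- unique(vapply(representatives, `[[`, "", "motion"))
  rows <- list()
  for (motion in motions) {
    sel <- Filter(function(r) r$motion == motion, representatives)
    for (mat in c("W", "H")) {
      # activation matrices are compared over their k waveforms, so they
      # enter the max-CC matching as samples x k (transposed)
      mats <- lapply(sel, function(r) {
        if (is.null(r[[mat]])) NULL else if (mat == "W") r$W else t(r$H)
      })
      if (any(vapply(mats, is.null, TRUE))) next
      grp <- vapply(sel, `[[`, "", "group")
      rep_sim <- group_similarity(list(CG = mats[grp == "CG"],
                                       SG = mats[grp == "SG"]))
      comb <- group_similarity(list(all = mats))
      vals <- c(intra_CG = unname(rep_sim$intra["CG"]),
                intra_SG = unname(rep_sim$intra["SG"]),
                intra_combined = unname(comb$intra["all"]),
                inter_CG_SG = rep_sim$inter["CG", "SG"])
      rows[[length(rows) + 1L]] <- data.frame(
        motion = motion, matrix = mat, measure = names(vals),
        similarity = unname(vals))
    }
  }
  do.call(rbind, rows)
}

#' End-to-end window classification of a preprocessed cohort
#'
#' Extracts per-window synergy features, optionally runs the two-stage
#' feature selection, and evaluates a rebalanced random forest with
#' stratified 10-fold cross-validation.
#'
#' @param processed Result of [preprocess_cohort()].
#' @param task `"motion"` (STD/ST/Gait label) or `"pathology"` (CG/SG).
#' @param k Synergy number per window.
#' @param features `"fine"`, `"coarse"` or `"selected"` (two-stage
#'   selection on the fine set).
#' @param n_folds,n_trees Cross-validation controls.
#' @param seed Seed for feature extraction, selection and CV.
#' @param feature_table Optional precomputed result of
#'   [cohort_window_features()] (fine set), reused across calls.
#' @param ... Passed to [cohort_window_features()].
#' @return A `classification_report` with attribute `selection` (the
#'   `selection_result` when `features = "selected"`) and attribute
#'   `feature_table`.
#' @export
classify_cohort <- function(processed, task = c("motion", "pathology"),
                            k = 2, features = c("fine", "coarse",
                                                "selected"),
                            n_folds = 10, n_trees = 30, seed = 1,
                            feature_table = NULL, ...) {
  task <- match.arg(task)
  features <- match.arg(features)
  base_set <- if (features == "coarse") "coarse" else "fine"
  if (is.null(feature_table)) {
    feature_table <- cohort_window_features(
      processed, k = k, feature_set = base_set,
      seed = derive_seed(seed, "features", k), ...)
  }
  label_cols <- c("motion", "group", "subject_id")
  X <- as.matrix(feature_table[, setdiff(names(feature_table),
                                         label_cols), drop = FALSE])
  y <- if (task == "motion") feature_table$motion else feature_table$group
  selection <- NULL
  if (features == "selected") {
    selection <- select_features(X, y, seed = derive_seed(seed, "sffs"))
    X <- X[, selection$stage2_selected, drop = FALSE]
  }
  report <- cross_validated_fm(X, y, n_trees = n_trees,
                               n_folds = n_folds,
                               seed = derive_seed(seed, "cv"),
                               task = task, feature_set = features)
  attr(report, "selection") <- selection
  attr(report, "feature_table") <- feature_table
  report
}
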