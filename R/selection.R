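#' Relief-F feature weights
#'
#' Instance-based feature weighting: iterating over every sample `R`
#' (m = sample count, no subsampling), each feature's weight is decreased
#' by its range-normalized distance to the nearest hit (same class) and
#' increased by the prior-weighted distances to the nearest misses of every
#' other class `C`, with weight `p(C) / (1 - p(class(R)))`. Nearest
#' neighbours are found under the Manhattan distance on range-normalized
#' features; features with zero range contribute zero distance and keep
#' weight 0.
#'
#' @param X Numeric matrix or data frame, samples x features.
#' @param y Class labels (coerced to factor), at least 2 classes with at
#'   least `k_neighbors + 1` samples each.
#' @param k_neighbors Nearest hits/misses per class (the source protocol
#'   uses 1).
#' @return Named numeric vector of Relief-F weights.
#' @export
relieff_weights <- function(X, y, k_neighbors = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  p <- ncol(X)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < k_neighbors + 1)) {
    stop("every class needs at least k_neighbors + 1 samples")
  }
  rng <- apply(X, 2, max) - apply(X, 2, min)
  scale <- ifelse(rng > 0, rng, Inf)  # zero-range features: diff == 0
  Xn <- sweep(X, 2, scale, "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  priors <- table(y) / n
  ri <- numeric(p)
  mk <- n * k_neighbors
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    for (cls in levels(y)) {
      idx <- which(y == cls)
      nn <- idx[order(d[idx], idx)[seq_len(k_neighbors)]]
      diffs <- rowSums(matrix(abs(Xn[i, ] - t(Xn[nn, , drop = FALSE])),
                              nrow = p))
      if (cls == as.character(y[i])) {
        ri <- ri - diffs / mk
      } else {
        w <- priors[[cls]] / (1 - priors[[as.character(y[i])]])
        ri <- ri + w * diffs / mk
      }
    }
  }
  names(ri) <- colnames(X)
  ri
}

#' Sequential floating forward feature selection
#'
#' Forward search with conditional backward elimination: at each step the
#' candidate whose addition maximizes the evaluator joins the selection;
#' afterwards any already-selected feature whose removal improves the
#' score is dropped. The search stops when no addition has improved the
#' best score for 3 consecutive steps (or candidates run out). Ties are
#' broken by feature-name order. The default evaluator is the mean
#' macro-averaged F-measure of a 30-tree random forest under seeded
#' stratified 5-fold cross-validation.
#'
#' @param X Samples x features matrix or data frame.
#' @param y Class labels.
#' @param candidate_features Feature names to search over (e.g. the
#'   Relief-F survivors).
#' @param evaluator Optional `function(feature_names) -> score`; failures
#'   score 0 with a warning.
#' @param seed Seed controlling the default evaluator's folds and forests
#'   (the whole search is deterministic given the seed).
#' @param patience Consecutive non-improving additions tolerated.
#' @return Character vector of selected names, with attribute `trace`
#'   (a data frame of step, action, feature and score).
#' @export
sffs_select <- function(X, y, candidate_features, evaluator = NULL,
                        seed = 1, patience = 3) {
  if (!length(candidate_features)) return(character(0))
  X <- as.data.frame(X)
  y <- factor(y)
  if (is.null(evaluator)) {
    evaluator <- function(feats) {
      rep <- cross_validated_fm(X[, feats, drop = FALSE], y,
                                n_trees = 30, n_folds = 5, seed = seed,
                                balance = FALSE)
      rep$mean_fm
    }
  }
  # the evaluator is deterministic given its seed, so every subset is
  # scored at most once (the floating step revisits many subsets)
  cache <- new.env(parent = emptyenv())
  score_of <- function(feats) {
    key <- paste(sort(feats), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(evaluator(feats), error = function(e) {
      warning("evaluator failed on {", paste(feats, collapse = ","),
              "}: ", conditionMessage(e))
      0
    })
    cache[[key]] <- val
    val
  }
  candidates <- sort(candidate_features)
  selected <- character(0)
  best_score <- -Inf
  best_set <- character(0)
  stall <- 0L
  trace <- list()
  note <- function(action, feature, score) {
    trace[[length(trace) + 1L]] <<-
      data.frame(action = action, feature = feature, score = score)
  }
  while (stall < patience) {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(f) score_of(c(selected, f)), 0)
    add <- remaining[which.max(scores)]
    current <- max(scores)
    selected <- c(selected, add)
    note("add", add, current)
    # conditional exclusion
    while (length(selected) > 2) {
      drop_scores <- vapply(selected, function(f) {
        score_of(setdiff(selected, f))
      }, 0)
      if (max(drop_scores) > current) {
        out <- selected[which.max(drop_scores)]
        current <- max(drop_scores)
        selected <- setdiff(selected, out)
        note("remove", out, current)
      } else break
    }
    if (current > best_score + 1e-12) {
      best_score <- current
      best_set <- selected
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  structure(best_set, trace = do.call(rbind, trace))
}

#' Two-stage feature selection: Relief-F screening then SFFS wrapper
#'
#' Stage 1 computes Relief-F weights and eliminates features with negative
#' weight (weights of exactly 0 are kept). Stage 2 runs the floating
#' forward wrapper search over the survivors.
#'
#' @param X Samples x features matrix or data frame.
#' @param y Class labels.
#' @param k_neighbors Relief-F neighbour count.
#' @param seed Wrapper seed.
#' @param ... Passed to [sffs_select()].
#' @return Object of class `selection_result`: list with `ri`,
#'   `stage1_kept`, `stage2_selected` and the `wrapper_trace`.
#' @export
select_features <- function(X, y, k_neighbors = 1, seed = 1, ...) {
  ri <- relieff_weights(X, y, k_neighbors)
  kept <- names(ri)[ri >= 0]
  sel <- sffs_select(X, y, kept, seed = seed, ...)
  structure(list(ri = ri, stage1_kept = kept,
                 stage2_selected = as.character(sel),
                 wrapper_trace = attr(sel, "trace")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d features -> %d after Relief-F -> %d selected\n",
    length(x$ri), length(x$stage1_kept), length(x$stage2_selected)))
  cat("  selected:", paste(x$stage2_selected, collapse = ", "), "\n")
  invisible(x)
}
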