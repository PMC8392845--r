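#' Rebalance classes to their geometric-mean size
#'
#' The per-class target count is the rounded geometric mean of the class
#' counts. Classes above target are reduced by random sampling with
#' replacement; classes below target are grown with ADASYN synthetic
#' samples (density-weighted interpolation towards nearest minority
#' neighbours, 5 neighbours), falling back to duplication when a class is
#' too small for neighbourhood estimation (< 6 samples).
#'
#' @param X Samples x features matrix or data frame (numeric).
#' @param y Class labels.
#' @param seed Optional seed.
#' @param k_neighbors ADASYN neighbourhood size.
#' @return List with rebalanced `X` (matrix) and `y` (factor); every
#'   class ends at the target count.
#' @export
balance_resample <- function(X, y, seed = NULL, k_neighbors = 5) {
  X <- as.matrix(X)
  y <- factor(y)
  counts <- table(y)
  if (length(counts) < 2) stop("need at least 2 classes")
  target <- round(exp(mean(log(counts))))
  with_seed(seed, {
    keep_X <- list()
    keep_y <- list()
    for (cls in levels(y)) {
      idx <- which(y == cls)
      n_c <- length(idx)
      if (n_c >= target) {
        take <- if (n_c == target) idx else
          sample(idx, target, replace = TRUE)
        keep_X[[cls]] <- X[take, , drop = FALSE]
      } else {
        G <- target - n_c
        if (n_c < 6) {
          warning("class ", cls, " too small for ADASYN; duplicating")
          synth <- X[sample(idx, G, replace = TRUE), , drop = FALSE]
        } else {
          synth <- adasyn_synthesize(X, y, cls, G, k_neighbors)
        }
        keep_X[[cls]] <- rbind(X[idx, , drop = FALSE], synth)
      }
      keep_y[[cls]] <- rep(cls, nrow(keep_X[[cls]]))
    }
    list(X = do.call(rbind, keep_X),
         y = factor(unlist(keep_y), levels = levels(y)))
  })
}

# ADASYN synthesis of G samples for minority class `cls`: seeds are drawn
# with probability proportional to the fraction of other-class samples
# among each minority point's k nearest neighbours (uniform when the class
# is cleanly separated), and each synthetic point is a random convex
# combination of its seed and one of the seed's nearest minority
# neighbours.
adasyn_synthesize <- function(X, y, cls, G, k_neighbors) {
  idx <- which(y == cls)
  D <- as.matrix(stats::dist(X))
  ratio <- vapply(idx, function(i) {
    d <- D[i, ]
    d[i] <- Inf
    nn <- order(d)[seq_len(k_neighbors)]
    mean(y[nn] != cls)
  }, 0)
  w <- if (sum(ratio) > 0) ratio / sum(ratio) else
    rep(1 / length(idx), length(idx))
  seeds <- sample(idx, G, replace = TRUE, prob = w)
  out <- matrix(0, G, ncol(X))
  for (g in seq_len(G)) {
    i <- seeds[g]
    d <- D[i, idx]
    d[idx == i] <- Inf
    nn <- idx[order(d)[seq_len(min(k_neighbors, length(idx) - 1L))]]
    z <- nn[sample.int(length(nn), 1L)]
    lam <- stats::runif(1)
    out[g, ] <- X[i, ] + lam * (X[z, ] - X[i, ])
  }
  colnames(out) <- colnames(X)
  out
}

#' Per-class precision, recall and F-measure from a confusion matrix
#'
#' With `n_ij` the number of samples of true class `i` identified as
#' class `j`: precision `P_i = n_ii / sum_j n_ji`, recall
#' `R_i = n_ii / sum_j n_ij`, and `FM_i = 2 P_i R_i / (P_i + R_i)`.
#' Empty denominators yield 0.
#'
#' @param confusion Square matrix, rows = true class, columns = predicted.
#' @return Data frame with columns `class`, `precision`, `recall`, `fm`.
#' @export
f_measure_report <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square")
  }
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(confusion)))
  P <- diag(confusion) / colSums(confusion)
  R <- diag(confusion) / rowSums(confusion)
  P[!is.finite(P)] <- 0
  R[!is.finite(R)] <- 0
  FM <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  data.frame(class = cls, precision = unname(P), recall = unname(R),
             fm = unname(FM))
}

#' Cross-validated random-forest F-measure
#'
#' Stratified seeded k-fold cross-validation of a random forest
#' (30 trees, `sqrt(p)` candidate features per split, unlimited depth,
#' majority vote). Rebalancing, when enabled, is applied to the training
#' portion of each fold only; test folds are never resampled. The
#' reported `mean_fm` is the mean over folds of the macro-averaged (i.e.
#' unweighted over classes) per-class F-measure.
#'
#' @param X Samples x features matrix or data frame (numeric features).
#' @param y Class labels; every class needs at least `n_folds` samples.
#' @param n_trees Trees per forest.
#' @param n_folds Folds.
#' @param seed Seed for fold assignment, rebalancing and forests.
#' @param balance Rebalance training folds with [balance_resample()].
#' @param task,feature_set Optional labels stored in the report.
#' @return Object of class `classification_report`: list with the pooled
#'   `confusion` matrix, `per_class` metrics (from the pooled confusion),
#'   `fold_fm`, `mean_fm`, `fold_count`, `task` and `feature_set`.
#' @export
cross_validated_fm <- function(X, y, n_trees = 30, n_folds = 10,
                               seed = 1, balance = TRUE,
                               task = NA_character_,
                               feature_set = NA_character_) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < n_folds)) {
    stop("stratification error: a class has fewer samples than folds")
  }
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    lev <- levels(y)
    confusion <- matrix(0L, length(lev), length(lev),
                        dimnames = list(true = lev, predicted = lev))
    fold_fm <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      if (balance) {
        bal <- balance_resample(Xtr, ytr)
        Xtr <- bal$X
        ytr <- bal$y
      }
      rf <- randomForest::randomForest(
        x = Xtr, y = ytr, ntree = n_trees,
        mtry = max(1, floor(sqrt(ncol(X)))))
      pred <- stats::predict(rf, X[!tr, , drop = FALSE])
      cm <- table(factor(y[!tr], levels = lev),
                  factor(pred, levels = lev))
      confusion <- confusion + cm
      fold_fm[f] <- mean(f_measure_report(cm)$fm)
    }
    structure(
      list(confusion = confusion,
           per_class = f_measure_report(confusion),
           fold_fm = fold_fm, mean_fm = mean(fold_fm),
           fold_count = n_folds, task = task,
           feature_set = feature_set),
      class = "classification_report")
  })
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report>%s%s %d-fold CV, mean FM = %.3f\n",
              if (is.na(x$task)) "" else paste0(" task=", x$task),
              if (is.na(x$feature_set)) "" else
                paste0(" features=", x$feature_set),
              x$fold_count, x$mean_fm))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
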