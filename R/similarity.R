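# Maximum correlation between W1 and ordered column selections of W2,
# together with the winning selection. Assumes ncol(W1) <= ncol(W2).
max_cc_align <- function(W1, W2) {
  k1 <- ncol(W1)
  v1 <- as.vector(W1)
  if (stats::sd(v1) == 0) {
    stop("undefined-CC error: constant matrix has zero variance")
  }
  best <- -Inf
  best_sel <- NULL
  for (sel in ordered_selections(ncol(W2), k1)) {
    v2 <- as.vector(W2[, sel, drop = FALSE])
    if (stats::sd(v2) == 0) next
    cc <- stats::cor(v1, v2)
    if (cc > best) {
      best <- cc
      best_sel <- sel
    }
  }
  if (!is.finite(best)) {
    stop("undefined-CC error: constant matrix has zero variance")
  }
  list(cc = best, selection = best_sel)
}

#' Maximum correlation coefficient between two synergy matrices
#'
#' For matrices `W1` (m x k1) and `W2` (m x k2) with `k1 <= k2` (arguments
#' are swapped otherwise), every ordered selection of `k1` columns of `W2`
#' is formed, the Pearson correlation between the column-stacked `W1` and
#' the selected matrix is computed, and the maximum over all selections is
#' returned. Column correspondence is thus part of the maximization, which
#' makes the measure invariant to synergy ordering.
#'
#' @param W1,W2 Synergy (or activation) matrices with equal row counts.
#' @return Maximum correlation coefficient in `[-1, 1]`.
#' @export
max_cc <- function(W1, W2) {
  W1 <- as.matrix(W1)
  W2 <- as.matrix(W2)
  if (nrow(W1) != nrow(W2)) {
    stop("order error: matrices must have the same row count")
  }
  if (ncol(W1) > ncol(W2)) {
    tmp <- W1; W1 <- W2; W2 <- tmp
  }
  if (ncol(W2) > 12) {
    stop("max_cc enumerates ordered column selections and supports at ",
         "most 12 columns; activation coefficient matrices must be ",
         "passed as samples x k (transposed)")
  }
  max_cc_align(W1, W2)$cc
}

#' Intra- and inter-group similarity of synergy matrices
#'
#' Intra-similarity of a group is the mean maximum correlation coefficient
#' over all unordered within-group pairs; inter-similarity of two groups
#' is the mean over the full cross-product of pairs (one matrix from each
#' group). Applies identically to synergy pattern and activation
#' coefficient matrices.
#'
#' @param groups Named list of lists of matrices; every group needs at
#'   least 2 members (intra-similarity is undefined for singletons).
#' @return Object of class `similarity_report`: list with the flattened
#'   `pairwise` max-CC matrix (diagonal 1), per-group `intra`, the
#'   group-pair `inter` matrix and the `labels`.
#' @export
group_similarity <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("undefined-intra error: group(s) with fewer than 2 matrices: ",
         paste(names(groups)[sizes < 2], collapse = ", "))
  }
  mats <- unlist(groups, recursive = FALSE)
  lab <- rep(names(groups), sizes)
  n <- length(mats)
  pw <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pw[i, j] <- pw[j, i] <- max_cc(mats[[i]], mats[[j]])
    }
  }
  intra <- vapply(names(groups), function(g) {
    idx <- which(lab == g)
    mean(pw[t(combn(idx, 2))])
  }, 0)
  gn <- names(groups)
  inter <- matrix(NA_real_, length(gn), length(gn),
                  dimnames = list(gn, gn))
  if (length(gn) > 1) {
    for (a in seq_along(gn)) {
      for (b in seq_along(gn)) {
        if (a < b) {
          inter[a, b] <- inter[b, a] <-
            mean(pw[which(lab == gn[a]), which(lab == gn[b])])
        }
      }
    }
  }
  structure(list(pairwise = pw, intra = intra, inter = inter,
                 labels = lab),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n  intra:",
      paste(sprintf("%s = %.3f", names(x$intra), x$intra),
            collapse = ", "), "\n")
  gn <- names(x$intra)
  if (length(gn) > 1) {
    pairs <- combn(gn, 2)
    cat("  inter:",
        paste(apply(pairs, 2, function(p) {
          sprintf("%s-%s = %.3f", p[1], p[2], x$inter[p[1], p[2]])
        }), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a representative synergy for one subject and motion
#'
#' Averages per-segment synergy pattern matrices after removing outliers:
#' each matrix's mean max-CC similarity `S_i` against the others is
#' computed, and matrices violating `|S_i - mean(S)| < 3 * sd(S)` are
#' dropped (when `sd(S) = 0` all matrices agree and none is dropped).
#' Surviving matrices are column-aligned to the first survivor via the
#' max-CC matching, averaged element-wise, and the averaged columns are
#' renormalized to unit norm. When the matching segment envelopes are
#' supplied, per-segment activation matrices are re-estimated against the
#' representative pattern and averaged into a representative activation.
#'
#' @param matrices List (length >= 2) of synergy pattern matrices from one
#'   subject x motion.
#' @param segments Optional list of envelope matrices matching
#'   `matrices`, used for the representative activation.
#' @param ... Passed to [estimate_activation()].
#' @return List with `W` (representative pattern), `H` (representative
#'   activation or `NULL`), `outliers` (dropped indices) and `S` (the
#'   per-matrix mean similarities).
#' @export
build_representative <- function(matrices, segments = NULL, ...) {
  n <- length(matrices)
  if (n < 2) stop("need at least 2 matrices")
  S <- vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i),
                function(j) max_cc(matrices[[i]], matrices[[j]]), 0))
  }, 0)
  dev <- stats::sd(S)
  keep <- if (dev < .Machine$double.eps^0.5) {
    seq_len(n)
  } else {
    which(abs(S - mean(S)) < 3 * dev)
  }
  if (!length(keep)) stop("internal error: all matrices flagged as outliers")
  ref <- matrices[[keep[1]]]
  aligned <- lapply(keep, function(i) {
    sel <- max_cc_align(ref, matrices[[i]])$selection
    matrices[[i]][, sel, drop = FALSE]
  })
  W <- Reduce(`+`, aligned) / length(aligned)
  nrm <- sqrt(colSums(W^2))
  nrm[nrm < 1e-300] <- 1
  W <- sweep(W, 2, nrm, "/")
  H <- NULL
  if (!is.null(segments)) {
    Hs <- lapply(segments, function(A) estimate_activation(A, W, ...))
    H <- Reduce(`+`, Hs) / length(Hs)
  }
  list(W = W, H = H, outliers = setdiff(seq_len(n), keep), S = S)
}
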