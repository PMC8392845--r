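#' Variability accounted for by a factorization
#'
#' `VAF = 1 - ||A - W %*% H||_F^2 / ||A - mean(A)||_F^2`, i.e. one minus
#' the ratio of residual to grand-mean-centered total sum of squares.
#'
#' @param A Envelope matrix.
#' @param W,H Factor matrices with conforming shapes.
#' @return VAF in `(-Inf, 1]`.
#' @export
compute_vaf <- function(A, W, H) {
  A <- as.matrix(A)
  denom <- sum((A - mean(A))^2)
  if (denom < .Machine$double.eps) {
    stop("undefined-VAF error: A is constant")
  }
  1 - sum((A - W %*% H)^2) / denom
}

# Non-negative double SVD initialization: leading singular triplets split
# into their positive/negative parts, the dominant part kept per component;
# zeros replaced by mean(A) * 1e-3 so multiplicative updates can move every
# entry.
nndsvd_init <- function(A, k) {
  sv <- svd(A, nu = k, nv = k)
  m <- nrow(A)
  n <- ncol(A)
  W <- matrix(0, m, k)
  H <- matrix(0, k, n)
  d <- c(sv$d, rep(0, k))
  W[, 1] <- sqrt(d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]
      v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      mp <- nup * nvp
      mn <- nun * nvn
      if (mp >= mn && mp > 0) {
        W[, j] <- sqrt(d[j] * mp) * up / nup
        H[j, ] <- sqrt(d[j] * mp) * vp / nvp
      } else if (mn > 0) {
        W[, j] <- sqrt(d[j] * mn) * un / nun
        H[j, ] <- sqrt(d[j] * mn) * vn / nvn
      }
    }
  }
  fill <- max(mean(A) * 1e-3, .Machine$double.eps)
  W[W <= 0] <- fill
  H[H <= 0] <- fill
  list(W = W, H = H)
}

#' Multi-restart multiplicative-update NMF of an envelope matrix
#'
#' Factorizes a non-negative envelope matrix `A` as `W %*% H` with the
#' Lee-Seung multiplicative updates under the Euclidean cost. After every
#' iteration each column of `W` is rescaled to unit Euclidean norm and the
#' matching row of `H` by the inverse factor (the product is unchanged),
#' keeping synergy patterns comparable across subjects. To reduce the risk
#' of poor local minima the updates are run from `n_random_restarts`
#' random initializations (entries uniform on (0, 1]) plus one
#' non-negative-double-SVD initialization; the run with maximal VAF wins
#' (ties: lowest run index).
#'
#' @param A Non-negative channels x samples matrix.
#' @param k Synergy count, `1 <= k <= nrow(A)`.
#' @param n_random_restarts Number of random initializations (the SVD
#'   start is always added).
#' @param max_iter Iteration cap per run.
#' @param tol Relative cost decrease below which a run stops.
#' @param seed Optional seed making the restarts reproducible.
#' @return Object of class `synergy_decomposition`: list with `W`
#'   (unit-norm columns), `H`, `vaf`, `k`, `init_kind` (`"random"` or
#'   `"svd"`), `iterations_run` and the winning run's `cost_trace`.
#' @export
nmf_decompose <- function(A, k, n_random_restarts = 20, max_iter = 1000,
                          tol = 1e-6, seed = NULL) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("domain error: A has negative entries")
  m <- nrow(A)
  if (k < 1 || k > m) {
    stop("order error: k must lie in 1..", m)
  }
  with_seed(seed, {
    best <- NULL
    run_one <- function(W0, H0, kind) {
      fit <- nmf_mu_cpp(A, W0, H0, max_iter, tol, FALSE)
      vaf <- compute_vaf(A, fit$W, fit$H)
      list(W = fit$W, H = fit$H, vaf = vaf, init_kind = kind,
           iterations_run = fit$iterations, cost_trace = fit$cost)
    }
    for (r in seq_len(n_random_restarts)) {
      W0 <- matrix(1 - stats::runif(m * k), m, k)
      H0 <- matrix(1 - stats::runif(k * ncol(A)), k, ncol(A))
      cand <- run_one(W0, H0, "random")
      if (is.null(best) || cand$vaf > best$vaf) best <- cand
    }
    init <- nndsvd_init(A, k)
    cand <- run_one(init$W, init$H, "svd")
    if (is.null(best) || cand$vaf > best$vaf) best <- cand
    # final safeguard: unit-norm columns even if a run ended on an H update
    nrm <- sqrt(colSums(best$W^2))
    nrm[nrm < 1e-300] <- 1
    best$W <- sweep(best$W, 2, nrm, "/")
    best$H <- best$H * nrm
    rownames(best$W) <- rownames(A)
    structure(c(best, list(k = k)), class = "synergy_decomposition")
  })
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf(
    "<synergy_decomposition> k = %d, VAF = %.4f (%s init, %d iterations)\n",
    x$k, x$vaf, x$init_kind, x$iterations_run))
  invisible(x)
}

#' Estimate activation coefficients for a fixed synergy pattern matrix
#'
#' Runs only the H multiplicative update against a fixed `W` (used when a
#' representative synergy pattern has already been determined), starting
#' from a uniform positive H, until the Euclidean cost converges.
#'
#' @param A Non-negative envelope matrix.
#' @param W_fixed Non-negative pattern matrix with unit-norm columns.
#' @param max_iter,tol Convergence controls as in [nmf_decompose()].
#' @return Non-negative activation matrix `H` (k x samples).
#' @export
estimate_activation <- function(A, W_fixed, max_iter = 1000, tol = 1e-6) {
  A <- as.matrix(A)
  W_fixed <- as.matrix(W_fixed)
  if (nrow(W_fixed) != nrow(A)) {
    stop("order error: W_fixed and A must have the same channel count")
  }
  if (any(W_fixed < 0)) stop("domain error: W_fixed has negative entries")
  H0 <- matrix(max(mean(A), 1e-8), ncol(W_fixed), ncol(A))
  fit <- nmf_mu_cpp(A, W_fixed, H0, max_iter, tol, TRUE)
  fit$H
}

#' Select the synergy number by the mean-VAF criterion
#'
#' Decomposes every segment for increasing `k` and returns the smallest
#' `k` whose mean VAF across segments exceeds `vaf_threshold`; if none
#' qualifies, returns `k_max` with a warning.
#'
#' @param segments Non-empty list of envelope matrices (channels x
#'   samples).
#' @param vaf_threshold Mean-VAF threshold (default 0.85).
#' @param k_max Largest synergy number tried (default: channel count).
#' @param ... Passed to [nmf_decompose()] (restarts, tolerances).
#' @param seed Optional seed for the whole selection run.
#' @return Integer `k` with attribute `mean_vaf`, the mean VAF for each
#'   `k` evaluated.
#' @export
select_synergy_number <- function(segments, vaf_threshold = 0.85,
                                  k_max = NULL, ..., seed = NULL) {
  if (!length(segments)) stop("input error: empty segment list")
  m <- nrow(as.matrix(segments[[1]]))
  if (is.null(k_max)) k_max <- m
  with_seed(seed, {
    mean_vaf <- numeric(0)
    for (k in seq_len(k_max)) {
      vafs <- vapply(segments, function(A) nmf_decompose(A, k, ...)$vaf, 0)
      mean_vaf[k] <- mean(vafs)
      if (mean_vaf[k] > vaf_threshold) {
        return(structure(as.integer(k), mean_vaf = mean_vaf))
      }
    }
    warning("no synergy number reached mean VAF > ", vaf_threshold,
            "; returning k_max = ", k_max)
    structure(as.integer(k_max), mean_vaf = mean_vaf)
  })
}
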