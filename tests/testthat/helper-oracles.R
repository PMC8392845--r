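# Independent oracles used across test files. These deliberately use naive
# loop-by-loop formulations so they share no code path with the package
# implementations they check.

# Literal transcription of the Relief-F update rule: iterate over every
# sample, subtract the nearest-hit range-normalized differences, add the
# prior-weighted nearest-miss differences per class.
relieff_oracle <- function(X, y, k = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2, max) - apply(X, 2, min)
  diff_a <- function(a, i, j) {
    if (rng[a] == 0) 0 else abs(X[i, a] - X[j, a]) / rng[a]
  }
  dist_ij <- function(i, j) sum(vapply(1:p, diff_a, 0, i = i, j = j))
  pri <- table(y) / n
  RI <- numeric(p)
  for (i in 1:n) {
    for (cls in sort(unique(y))) {
      cand <- setdiff(which(y == cls), i)
      d <- vapply(cand, function(j) dist_ij(i, j), 0)
      nn <- cand[order(d, cand)][seq_len(k)]
      for (a in 1:p) {
        s <- sum(vapply(nn, function(j) diff_a(a, i, j), 0))
        if (cls == y[i]) {
          RI[a] <- RI[a] - s / (n * k)
        } else {
          RI[a] <- RI[a] + pri[[cls]] / (1 - pri[[y[i]]]) * s / (n * k)
        }
      }
    }
  }
  RI
}

# Brute-force maximum correlation over all ordered column selections,
# enumerated with explicit nested loops (k1 <= 3 in the tests).
max_cc_oracle <- function(W1, W2) {
  k1 <- ncol(W1)
  k2 <- ncol(W2)
  best <- -Inf
  idx <- seq_len(k2)
  pick <- function(sel) {
    cc <- suppressWarnings(cor(as.vector(W1),
                               as.vector(W2[, sel, drop = FALSE])))
    if (is.finite(cc) && cc > best) best <<- cc
  }
  if (k1 == 1) {
    for (a in idx) pick(a)
  } else if (k1 == 2) {
    for (a in idx) for (b in setdiff(idx, a)) pick(c(a, b))
  } else if (k1 == 3) {
    for (a in idx) for (b in setdiff(idx, a)) {
      for (c3 in setdiff(idx, c(a, b))) pick(c(a, b, c3))
    }
  } else {
    stop("oracle supports k1 <= 3")
  }
  best
}

# A small non-negative planted factorization: random unit-norm W and
# temporally bumped H, plus optional Gaussian envelope noise.
planted_factorization <- function(m = 4, k = 2, n = 100, noise_sd = 0,
                                  seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(m * k, 0.05, 1), m, k)
  # push columns towards distinct channels so the factorization is
  # identifiable
  for (j in seq_len(k)) {
    lead <- ((j - 1) %% m) + 1
    W[lead, j] <- W[lead, j] + 2
  }
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  H <- matrix(0, k, n)
  t <- seq_len(n)
  for (j in seq_len(k)) {
    H[j, ] <- exp(-0.5 * ((t - (j - 0.5) / k * n) / (n / (4 * k)))^2)
  }
  A <- W %*% H
  if (noise_sd > 0) {
    A <- pmax(A + noise_sd * max(A) * matrix(stats::rnorm(m * n), m), 0)
  }
  list(A = A, W = W, H = H)
}
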