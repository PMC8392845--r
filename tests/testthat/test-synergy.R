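test_that("VAF has its defining values and invariances", {
  A <- matrix(c(1, 3, 2, 4), 2)
  # exact reconstruction
  expect_equal(compute_vaf(A, A, diag(2)), 1)
  # hand-computed: W2 %*% H2 = [[1,2],[3,3]], residual 1, centered total 5
  W2 <- matrix(c(1, 3, 2, 3), 2)
  H2 <- diag(2)
  expect_equal(compute_vaf(A, W2, H2), 0.8)
  # invariant to compensated rescaling of the factors
  expect_equal(compute_vaf(A, W2 * 7, H2 / 7), 0.8)
  expect_error(compute_vaf(matrix(2, 3, 3), W2, H2), "constant")
})

test_that("an exact rank-1 matrix is recovered with VAF ~ 1", {
  set.seed(2)
  A <- outer(c(1, 2, 3, 0.5), runif(60))
  d <- nmf_decompose(A, 1, n_random_restarts = 5, seed = 1)
  expect_gte(d$vaf, 0.999)
  expect_true(all(d$W >= 0) && all(d$H >= 0))
  expect_equal(sum(d$W^2), 1, tolerance = 1e-9)
})

test_that("the multiplicative-update cost never increases", {
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(runif(4 * 50), 4)
    d <- nmf_decompose(A, 2, n_random_restarts = 3, seed = s)
    expect_true(all(diff(d$cost_trace) <= 1e-10 * d$cost_trace[1]))
  }
})

test_that("planted factorizations are recovered under small noise", {
  for (k in 2:3) {
    pf <- planted_factorization(m = 4, k = k, n = 100, noise_sd = 0.02,
                                seed = k)
    d <- nmf_decompose(pf$A, k, seed = 10 + k)
    expect_gte(max_cc(d$W, pf$W), 0.95)
    expect_equal(d$vaf, compute_vaf(pf$A, d$W, d$H), tolerance = 1e-12)
  }
})

test_that("decomposition is bit-reproducible under a fixed seed", {
  pf <- planted_factorization(seed = 6)
  d1 <- nmf_decompose(pf$A, 2, seed = 42)
  d2 <- nmf_decompose(pf$A, 2, seed = 42)
  expect_identical(d1$W, d2$W)
  expect_identical(d1$H, d2$H)
  expect_identical(d1$vaf, d2$vaf)
})

test_that("domain and order errors are raised", {
  A <- matrix(runif(20), 4)
  A[1] <- -1
  expect_error(nmf_decompose(A, 2), "negative")
  expect_error(nmf_decompose(abs(A), 5), "order error")
})

test_that("fixed-pattern activation estimation recovers the exact model", {
  set.seed(8)
  w <- matrix(c(0.2, 0.5, 0.8, 0.3), 4)
  w <- w / sqrt(sum(w^2))
  h_true <- matrix(runif(80, 0.1, 1), 1)
  A <- w %*% h_true
  H <- estimate_activation(A, w, max_iter = 5000, tol = 1e-12)
  expect_lt(sqrt(mean((H - h_true)^2)) / sqrt(mean(h_true^2)), 0.01)
  expect_true(all(H >= 0))
  H0 <- estimate_activation(matrix(0, 4, 30), w)
  expect_true(all(H0 < 1e-6))
})

test_that("the synergy-number rule returns 1 for exact rank-1 segments", {
  set.seed(3)
  segs <- lapply(1:4, function(i) outer(runif(4, 0.2, 1), runif(50)))
  k <- select_synergy_number(segs, n_random_restarts = 3, seed = 1)
  expect_equal(as.integer(k), 1L)
  expect_gt(attr(k, "mean_vaf")[1], 0.999)
  expect_error(select_synergy_number(list()), "empty")
})

test_that("mean VAF is non-decreasing in the synergy number", {
  set.seed(9)
  segs <- lapply(1:3, function(i) matrix(runif(4 * 60), 4))
  vafs <- vapply(1:4, function(k) {
    mean(vapply(segs, function(A) {
      nmf_decompose(A, k, n_random_restarts = 5, seed = k)$vaf
    }, 0))
  }, 0)
  expect_true(all(diff(vafs) > -0.01))
})
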