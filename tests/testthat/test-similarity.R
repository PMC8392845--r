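test_that("max_cc has its self- and permutation-identities", {
  set.seed(1)
  W <- matrix(runif(8), 4)
  expect_equal(max_cc(W, W), 1)
  expect_equal(max_cc(W, W[, c(2, 1)]), 1)
  expect_error(max_cc(matrix(1, 4, 2), W), "undefined-CC")
  expect_error(max_cc(W, matrix(runif(6), 3)), "row count")
})

test_that("max_cc equals exhaustive enumeration over ordered selections", {
  W1 <- matrix(c(1, 0, 0, 1), 2)
  W2 <- cbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_equal(max_cc(W1, W2), max_cc_oracle(W1, W2))
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(runif(4 * 2), 4)
    B <- matrix(runif(4 * 3), 4)
    expect_equal(max_cc(A, B), max_cc_oracle(A, B), tolerance = 1e-12)
    # symmetry (argument order must not matter)
    expect_equal(max_cc(A, B), max_cc(B, A), tolerance = 1e-12)
  }
})

test_that("group similarity averages the right pair sets", {
  set.seed(2)
  base <- matrix(runif(8), 4)
  same <- list(base, base, base)
  rep1 <- group_similarity(list(G = same))
  expect_equal(unname(rep1$intra["G"]), 1)
  g1 <- lapply(1:2, function(i) matrix(runif(8), 4))
  g2 <- lapply(1:3, function(i) matrix(runif(8), 4))
  rep2 <- group_similarity(list(a = g1, b = g2))
  # oracle: brute-force double loop over the 6 cross pairs
  cross <- mean(vapply(g1, function(x) {
    mean(vapply(g2, function(y) max_cc(x, y), 0))
  }, 0))
  expect_equal(rep2$inter["a", "b"], cross, tolerance = 1e-12)
  expect_equal(unname(rep2$intra["a"]), max_cc(g1[[1]], g1[[2]]))
  # ordering within a group must not matter
  rep3 <- group_similarity(list(a = g1, b = rev(g2)))
  expect_equal(rep3$intra, rep2$intra)
  expect_equal(rep3$inter["a", "b"], rep2$inter["a", "b"])
  expect_error(group_similarity(list(a = g1, b = g2[1])), "undefined-intra")
})

test_that("representative building removes a planted outlier and only it", {
  set.seed(3)
  base <- sweep(matrix(c(1, 0.1, 0.05, 0.02, 0.02, 0.05, 0.1, 1), 4), 2,
                c(1, 1), "/")
  # a lone outlier among n matrices can deviate at most (n-1)/sqrt(n)
  # standard deviations from the mean, so the 3-sigma rule needs n >= 11
  # members to be able to fire at all; 15 clean + 1 planted keeps a margin
  mats <- lapply(1:15, function(i) {
    M <- pmax(base + matrix(rnorm(8, sd = 0.01), 4), 0)
    sweep(M, 2, sqrt(colSums(M^2)), "/")
  })
  outlier <- matrix(c(0, 1, 0.1, 0, 0.3, 0, 0, 0.9), 4)
  mats[[16]] <- sweep(outlier, 2, sqrt(colSums(outlier^2)), "/")
  rep <- build_representative(mats)
  expect_equal(rep$outliers, 16L)
  expect_equal(colSums(rep$W^2), rep(1, 2), tolerance = 1e-9)
  # oracle: S_i computed by enumeration flags only the planted matrix
  S <- vapply(1:16, function(i) {
    mean(vapply(setdiff(1:16, i), function(j) max_cc(mats[[i]], mats[[j]]),
                0))
  }, 0)
  expect_equal(rep$S, S, tolerance = 1e-12)
  expect_true(abs(S[16] - mean(S)) >= 3 * sd(S))
  expect_true(all(abs(S[1:15] - mean(S)) < 3 * sd(S)))
})

test_that("identical matrices give a degenerate spread and no outliers", {
  W <- sweep(matrix(runif(8, 0.1, 1), 4), 2, 1, "/")
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  mats <- list(W, W, W, W)
  rep <- build_representative(mats)
  expect_length(rep$outliers, 0)
  expect_equal(rep$W, W, tolerance = 1e-9)
})

test_that("representative activations average the re-estimated segments", {
  set.seed(5)
  pf <- planted_factorization(m = 4, k = 2, n = 60, seed = 11)
  segs <- list(pf$A, pf$A)
  mats <- list(pf$W, pf$W)
  rep <- build_representative(mats, segs, max_iter = 3000, tol = 1e-10)
  expect_equal(dim(rep$H), c(2L, 60L))
  # with W_rep = W_true the re-estimated activation tracks H_true
  expect_gt(cor(as.vector(rep$H), as.vector(pf$H)), 0.99)
})
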