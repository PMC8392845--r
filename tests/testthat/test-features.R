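test_that("window counts and starts follow the 192-sample step", {
  env <- matrix(runif(4 * 640), 4)
  w1 <- window_stream(env[, 1:256, drop = FALSE])
  expect_length(w1, 1L)
  w3 <- window_stream(env)
  expect_length(w3, 3L)
  expect_equal(vapply(w3, attr, 0L, "start"), c(0L, 192L, 384L))
  # neighbours share exactly 64 samples
  expect_identical(w3[[1]][, 193:256], w3[[2]][, 1:64])
  expect_warning(w0 <- window_stream(env[, 1:100, drop = FALSE]), "window")
  expect_length(w0, 0L)
})

test_that("activation ratios order synergies and preserve the product", {
  H1 <- matrix(runif(50), 1)
  expect_equal(reorder_by_activation_ratio(matrix(runif(4), 4), H1)$r, 1)
  W <- matrix(runif(8), 4)
  H <- rbind(rep(3, 40), rep(1, 40))
  ro <- reorder_by_activation_ratio(W, H)
  expect_equal(ro$r, c(0.75, 0.25))
  expect_equal(ro$W, W)
  set.seed(4)
  W2 <- matrix(runif(12), 4)
  H2 <- matrix(runif(3 * 30), 3)
  ro2 <- reorder_by_activation_ratio(W2, H2)
  expect_equal(sum(ro2$r), 1)
  expect_true(all(diff(ro2$r) <= 0))
  expect_equal(ro2$W %*% ro2$H, W2 %*% H2)
  expect_error(reorder_by_activation_ratio(W, matrix(0, 2, 5)),
               "all zero")
})

test_that("time-domain features of a constant activation have closed forms", {
  W <- matrix(runif(4), 4)
  H <- matrix(0.7, 1, 100)
  expect_warning(f <- extract_features(W, H, "fine"), "constant")
  expect_equal(unname(f["MAV1"]), 0.7)
  expect_equal(unname(f["rms1"]), 0.7)
  expect_equal(unname(f["WL1"]), 0)
  expect_equal(unname(f["IQR1"]), 0)
  expect_equal(unname(f[c("AR21", "AR31", "AR41", "AR51")]), rep(0, 4))
})

test_that("IQR follows the type-7 quartile rule", {
  W <- matrix(runif(4), 4)
  H <- matrix(1:100, 1, 100)
  f <- extract_features(W, H, "fine")
  # rank-statistic oracle on 1..100: Q1 = 25.75, Q3 = 75.25
  expect_equal(unname(f["IQR1"]), 49.5)
})

test_that("a known AR(4) process is refit within 10%", {
  a <- c(-2.2, 2.0, -0.9, 0.2)  # h_t = -sum a_i h_{t-i} + e_t
  set.seed(6)
  h <- as.numeric(stats::arima.sim(list(ar = -a), n = 100))
  W <- matrix(runif(4), 4)
  f <- extract_features(W, matrix(h, 1), "fine")
  fitted <- unname(f[c("AR21", "AR31", "AR41", "AR51")])
  expect_lt(max(abs(fitted - a)), 0.1 * max(abs(a)))
})

test_that("feature vectors have the printed lengths and names", {
  set.seed(6)
  for (k in 2:3) {
    W <- matrix(runif(4 * k), 4)
    H <- matrix(runif(k * 100) + 0.1, k)
    coarse <- extract_features(W, H, "coarse")
    fine <- extract_features(W, H, "fine")
    expect_length(coarse, 4 * k)
    expect_length(fine, 4 * k + 8 * k)
    expect_equal(names(coarse)[1:4], c("W11", "W12", "W13", "W14"))
    expect_true(all(coarse >= 0))
    expect_true(all(c(paste0("rms", k), paste0("AR5", k),
                      paste0("WL", k)) %in% names(fine)))
    expect_true(all(is.finite(fine)))
  }
})
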