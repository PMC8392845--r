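test_that("rebalancing targets the geometric mean of class sizes", {
  set.seed(1)
  X <- matrix(rnorm(500 * 3), 500)
  y <- rep(c("min", "maj"), times = c(100, 400))
  bal <- balance_resample(X, y, seed = 2)
  expect_equal(as.integer(table(bal$y)), c(200L, 200L))
  # already balanced classes keep their sizes
  yb <- rep(c("a", "b"), each = 50)
  balb <- balance_resample(X[1:100, ], yb, seed = 3)
  expect_equal(as.integer(table(balb$y)), c(50L, 50L))
})

test_that("ADASYN synthetics interpolate within the minority class box", {
  set.seed(4)
  Xmin <- matrix(runif(20 * 2, 0, 1), 20)
  Xmaj <- matrix(runif(80 * 2, 2, 3), 80)
  X <- rbind(Xmin, Xmaj)
  y <- rep(c("min", "maj"), times = c(20, 80))
  bal <- balance_resample(X, y, seed = 5)
  target <- round(sqrt(20 * 80))
  expect_equal(as.integer(table(bal$y)), rep(target, 2))
  synth <- bal$X[bal$y == "min", ][-(1:20), , drop = FALSE]
  expect_true(all(synth >= min(Xmin) - 1e-12 & synth <= max(Xmin) + 1e-12))
  # tiny classes fall back to duplication, with a warning
  expect_warning(
    b2 <- balance_resample(X[c(1:4, 21:60), ], y[c(1:4, 21:60)], seed = 6),
    "ADASYN")
  expect_equal(length(unique(as.integer(table(b2$y)))), 1L)
})

test_that("F-measures follow the precision/recall arithmetic", {
  diagm <- diag(c(5, 8, 2))
  r <- f_measure_report(diagm)
  expect_equal(r$precision, rep(1, 3))
  expect_equal(r$fm, rep(1, 3))
  cm <- matrix(c(8, 3, 2, 7), 2)  # rows true, cols predicted
  r2 <- f_measure_report(cm)
  P <- c(8 / 11, 7 / 9)
  R <- c(8 / 10, 7 / 10)
  expect_equal(r2$precision, P)
  expect_equal(r2$recall, R)
  expect_equal(r2$fm, 2 * P * R / (P + R))
  # harmonic-mean bound on random confusions
  set.seed(7)
  for (i in 1:5) {
    cmr <- matrix(rpois(9, 5), 3)
    rr <- f_measure_report(cmr)
    expect_true(all(rr$fm <= pmax(rr$precision, rr$recall) + 1e-12))
  }
  # an empty true class reports zero recall, not NaN
  r3 <- f_measure_report(matrix(c(3, 0, 1, 0), 2))
  expect_equal(r3$recall[2], 0)
  expect_equal(r3$fm[2], 0)
})

test_that("cross-validation separates what is separable and not more", {
  set.seed(8)
  n <- 200
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(rnorm(n, ifelse(y == "a", 0, 4)), rnorm(n))
  rep1 <- cross_validated_fm(X, y, seed = 9)
  expect_gte(rep1$mean_fm, 0.95)
  expect_equal(sum(rep1$confusion), n)
  # chance level on permuted labels
  yperm <- sample(y)
  rep2 <- cross_validated_fm(X, yperm, seed = 10)
  expect_lt(abs(rep2$mean_fm - 0.5), 0.1)
  # determinism
  rep3 <- cross_validated_fm(X, y, seed = 9)
  expect_identical(rep1$confusion, rep3$confusion)
  expect_identical(rep1$fold_fm, rep3$fold_fm)
  sub <- c(1:6, 101:106)
  expect_error(cross_validated_fm(X[sub, ], y[sub], n_folds = 10),
               "stratification")
})

test_that("the pathology task is learnable when groups differ", {
  spec <- synth_spec(n_subjects = 2, reps = 2, seed = 31)
  cohort <- generate_cohort(spec)
  keep <- grepl("_ST$|_STD$", names(cohort))
  pr <- preprocess_cohort(lapply(cohort[keep], `[[`, "recording"))
  ft <- cohort_window_features(pr, k = 2, feature_set = "fine", seed = 5)
  X <- as.matrix(ft[, setdiff(names(ft),
                              c("motion", "group", "subject_id"))])
  expect_equal(ncol(X), 24L)
  rep <- cross_validated_fm(X, ft$group, seed = 6, task = "pathology",
                            feature_set = "fine")
  expect_gte(rep$mean_fm, 0.85)
})
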