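test_that("filtering and rectification behave linearly and non-negatively", {
  expect_equal(filter_and_rectify(rep(0, 2000), 1000), rep(0, 2000))
  set.seed(1)
  out <- filter_and_rectify(rnorm(2000), 1000)
  expect_length(out, 2000)
  expect_true(all(out >= 0))
  expect_error(filter_and_rectify(rnorm(1000), fs = 900), "Nyquist")
})

test_that("a 5 Hz tone is attenuated as the filter response predicts", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)
  y <- filter_and_rectify(x, fs)
  # oracle: squared magnitude response (forward-backward) at 5 Hz,
  # evaluated directly from the transfer-function polynomials
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 5 / fs)
  gain <- Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
                sum(bf$a * z^(seq_along(bf$a) - 1)))^2
  expect_lt(gain, 0.05)
  core <- y[(fs + 1):(9 * fs)] # trim filter edge transients
  expect_lt(sqrt(mean(core^2)), 0.05 * sqrt(mean(x^2)))
})

test_that("envelope normalization and RMS smoothing have their closed forms", {
  fs <- 1000
  const <- matrix(3, 1, 500)
  env <- normalize_and_envelope(const, fs, session_max = 3)
  expect_equal(as.numeric(env), rep(1, 500), tolerance = 1e-12)
  # a unit impulse smoothed by an L-sample RMS window reads sqrt(1/L)
  L <- round(100 * fs / 1000)
  x <- matrix(0, 1, 1000)
  x[1, 500] <- 1
  env2 <- normalize_and_envelope(x, fs, session_max = 1)
  covered <- which(abs(env2[1, ] - sqrt(1 / L)) < 1e-12)
  expect_equal(length(covered), L)
  expect_true(500 %in% covered)
  expect_error(
    normalize_and_envelope(rbind(RF = rep(1, 10), FB = rep(0, 10)), fs,
                           session_max = c(1, 0)),
    "FB")
})

test_that("bell-shaped repetitions segment exactly where a speed-trace scan says", {
  fs <- 1000
  t2 <- seq_len(2 * fs)
  rise <- 5 + 60 * 0.5 * (1 - cos(pi * t2 / length(t2)))
  bell <- c(rise, rep(65, 2 * fs), rev(rise))
  angle <- c(rep(5, 3 * fs), bell, rep(5, 3 * fs))
  seg <- segment_motion(angle, fs, "STD")
  expect_equal(nrow(seg), 1L)
  # oracle: exhaustive forward scan of the smoothed speed trace
  w <- 100L
  n <- length(angle)
  cs <- cumsum(c(0, angle))
  lo <- pmax(seq_len(n) - 49L, 1L)
  hi <- pmin(seq_len(n) + 50L, n)
  s <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  v <- c(s[2] - s[1], (s[3:n] - s[1:(n - 2)]) / 2, s[n] - s[n - 1]) * fs
  p <- which.max(s)
  thr1 <- 0.10 * max(abs(v[1:p]))
  start <- which(abs(v[1:p]) >= thr1)[1]
  tpk <- p + which.max(abs(v[p:n])) - 1L
  thr2 <- 0.10 * max(abs(v[p:n]))
  end <- tpk + which(abs(v[tpk:n]) < thr2)[1] - 1L
  expect_equal(seg$start, start - 1L)
  expect_equal(seg$end, end)
})

test_that("gait cycles are cut at the first minimum after each angle maximum", {
  spec <- synth_spec(n_subjects = 1, reps = 8, seed = 7)
  g <- generate_recording(spec, "G1", "CG", "Gait")
  seg <- segment_motion(g$recording$angle, spec$fs, "Gait")
  expect_true(nrow(seg) %in% c(7L, 8L))
  smoothed <- as.numeric(stats::filter(g$recording$angle, rep(1, 101) / 101,
                                       sides = 2))
  for (i in seq_len(nrow(seg))) {
    piece <- smoothed[(seg$start[i] + 1):seg$end[i]]
    # exactly one planted swing peak (one contiguous run above 45 deg)
    runs <- rle(piece > 45)
    expect_equal(sum(runs$values), 1L)
  }
  durations <- (seg$end - seg$start) / spec$fs
  expect_lt(abs(mean(durations) - 1.32), 0.1)
})

test_that("degenerate angle traces yield an empty segment list", {
  expect_warning(seg <- segment_motion(rep(10, 2000), 1000, "STD"), "flat")
  expect_equal(nrow(seg), 0L)
})

test_that("segment resampling is exact linear interpolation", {
  m <- matrix(runif(200), 2, 100)
  expect_equal(resample_segment(m, 100), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(resample_segment(matrix(2, 3, 57), 100),
               matrix(2, 3, 100), tolerance = 1e-12, ignore_attr = TRUE)
  ramp <- matrix(seq(0, 1, length.out = 50), 1, 50)
  out <- resample_segment(ramp, 100)
  expect_lt(max(abs(out[1, ] - seq(0, 1, length.out = 100))), 1e-9)
  expect_error(resample_segment(matrix(1, 2, 1)), "degenerate")
})
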