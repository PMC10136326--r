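test_that("band-pass keeps the passband, rejects DC and mains-range power", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  dc <- eeg_bandpass(rep(50, length(t)), fs)
  expect_lt(mean(abs(dc[(2 * fs):(18 * fs)])), 0.5)
  inb <- eeg_bandpass(sin(2 * pi * 10 * t), fs)
  mid <- inb[(5 * fs):(15 * fs)]
  expect_gt(max(abs(mid)), 0.95)            # < 5% attenuation at 10 Hz
  outb <- eeg_bandpass(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(outb[(5 * fs):(15 * fs)])), 0.1)  # > 90% at 50 Hz
  expect_error(eeg_bandpass(t, fs = 70), "twice")
})

test_that("the window grid covers the signal with fully-contained windows", {
  g <- make_grid(10 * 250, 250, 2, 1)
  expect_equal(g$starts, 0:8)
  expect_equal(length(make_grid(2 * 250, 250, 2, 1)$starts), 1L)
  expect_error(make_grid(475, 250, 2, 1), "shorter")
})

test_that("the feature catalogue has 67 features in the four families", {
  fn <- eeg_feature_names()
  expect_equal(nrow(fn), 67L)
  expect_equal(as.vector(table(fn$family)[c("time", "frequency", "entropy",
                                            "asymmetry")]),
               c(24L, 16L, 8L, 19L))
  fs <- 250
  x1 <- gen_background_eeg(20, fs, 20, seed = 1)
  x2 <- gen_background_eeg(20, fs, 20, seed = 2)
  g <- make_grid(length(x1), fs, 2, 1)
  F1 <- extract_eeg_features(x1, x2, fs, g)
  expect_equal(colnames(F1), fn$name)
  expect_true(all(is.finite(F1)))
})

test_that("degenerate and pure-tone windows produce the documented values", {
  fs <- 250
  zeros <- numeric(2 * fs)
  g <- make_grid(length(zeros), fs, 2, 1)
  Fz <- extract_eeg_features(zeros, zeros, fs, g)
  expect_equal(unname(Fz[1, "ch1_line_length"]), 0)
  expect_equal(unname(Fz[1, "ch1_rms"]), 0)
  expect_equal(unname(Fz[1, c("ch1_relpow_delta", "ch1_relpow_theta",
                              "ch1_relpow_alpha", "ch1_relpow_beta")]),
               rep(0.25, 4), ignore_attr = TRUE)

  tone <- sin(2 * pi * 6 * (0:(2 * fs - 1)) / fs)
  Ft <- extract_eeg_features(tone, tone, fs, g)
  bands <- Ft[1, c("ch1_relpow_delta", "ch1_relpow_theta",
                   "ch1_relpow_alpha", "ch1_relpow_beta")]
  expect_equal(names(which.max(bands)), "ch1_relpow_theta")

  xin <- tone; xin[17] <- NaN
  expect_error(extract_eeg_features(xin, tone, fs, g), "window")
})

test_that("the documented feature subset is invariant to amplitude rescaling", {
  fs <- 250
  x1 <- gen_background_eeg(30, fs, 20, seed = 5)
  x2 <- gen_background_eeg(30, fs, 20, seed = 6)
  g <- make_grid(length(x1), fs, 2, 1)
  A <- extract_eeg_features(x1, x2, fs, g)
  B <- extract_eeg_features(3.7 * x1, 3.7 * x2, fs, g)
  fn <- eeg_feature_names()
  inv <- fn$name[fn$scale_invariant]
  expect_equal(A[, inv], B[, inv], tolerance = 1e-6)
  # amplitude features are covariant with the rescaling
  for (nm in c("ch1_rms", "ch1_line_length", "ch2_mean_abs"))
    expect_equal(B[, nm], 3.7 * A[, nm], tolerance = 1e-8)
})

test_that("window classifier separates separable data and persists", {
  set.seed(1)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 6), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(FALSE, TRUE), each = 100)
  m <- train_eeg_classifier(x, y)
  pr <- predict(m, x)
  expect_equal(pr$positive, y)              # 100% training accuracy
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, f)
  pr2 <- predict(readRDS(f), x)
  expect_identical(pr$decision, pr2$decision)
  expect_error(train_eeg_classifier(x, rep(TRUE, 200)), "single class")
})

test_that("8-of-10 post-processing matches its contract on the examples", {
  # 8 positives inside the first 10 windows -> one minimum-length event
  x <- c(rep(1, 8), rep(0, 12))
  ev <- postprocess(x)
  expect_equal(ev[, c("start_s", "end_s")],
               data.frame(start_s = 0, end_s = 10))
  expect_equal(nrow(postprocess(rep(0, 30))), 0L)
  # 20 consecutive positives -> qualifying groups 0..10 union to [0, 20)
  ev2 <- postprocess(rep(1, 20))
  expect_equal(ev2[, c("start_s", "end_s")],
               data.frame(start_s = 0, end_s = 20))
  # never 8-of-10 -> nothing
  x3 <- rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_equal(nrow(postprocess(x3)), 0L)
  # fewer windows than a group is silent, not an error
  expect_equal(nrow(postprocess(rep(1, 5))), 0L)
})

test_that("post-processing agrees with the naive group-enumeration oracle", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(10:40, 1)
    x <- rbinom(n, 1, runif(1, 0.3, 0.9))
    got <- postprocess(x)
    want <- naive_postprocess(x)
    expect_equal(got[, c("start_s", "end_s")], want)
  }
})

test_that("adding a positive window never shrinks the detections", {
  set.seed(8)
  for (i in 1:100) {
    x <- rbinom(30, 1, 0.6)
    ev <- postprocess(x)
    j <- sample(which(x == 0), 1)
    x2 <- x; x2[j] <- 1
    ev2 <- postprocess(x2)
    dur <- function(e) sum(e$end_s - e$start_s)
    expect_gte(dur(ev2), dur(ev))
    # previous coverage is preserved
    for (k in seq_len(nrow(ev)))
      expect_true(any(ev2$start_s <= ev$start_s[k] &
                        ev$end_s[k] <= ev2$end_s))
    # durations are >= 10 s and integer multiples of the hop
    expect_true(all(ev2$end_s - ev2$start_s >= 10))
    expect_true(all((ev2$end_s - ev2$start_s) %% 1 == 0))
  }
})
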