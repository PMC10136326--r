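test_that("R-peak detectors locate impulse trains and reject flat signals", {
  fs <- 250
  x <- numeric(30 * fs)
  x[seq(1, length(x), by = fs)] <- 1        # unit impulses at 1 Hz
  for (m in c("pan_tompkins", "local_max")) {
    pk <- detect_rpeaks(x, fs, m)
    expect_gt(length(pk$peak_times_s), 25)
    gaps <- diff(pk$peak_times_s)
    expect_true(all(abs(gaps - 1) <= 1 / fs + 1e-9))
    expect_warning(detect_rpeaks(numeric(11 * fs), fs, m), "flat")
  }
  expect_error(detect_rpeaks(numeric(5 * fs), fs), "10 s")
})

test_that("the ensemble keeps majority-supported peaks at their centroid", {
  mk <- function(t, id) structure(list(peak_times_s = t, detector_id = id),
                                  class = "ws_rpeaks")
  a <- mk(c(1, 2, 3), "a")
  expect_warning(out <- ensemble_rpeaks(list(a)), "single")
  expect_equal(out$peak_times_s, c(1, 2, 3))
  expect_equal(ensemble_rpeaks(list(a, mk(c(1, 2, 3), "b")))$peak_times_s,
               c(1, 2, 3))
  # 3 detectors: a peak seen by 2 is kept, by only 1 dropped
  out3 <- ensemble_rpeaks(list(mk(c(1, 2), "a"), mk(c(1.02, 2.01, 5), "b"),
                               mk(c(0.99), "c")))
  expect_equal(length(out3$peak_times_s), 2L)
  expect_true(all(abs(out3$peak_times_s - c(1, 2)) < 0.05))
  # jittered copies of a truth stay within the jitter of the truth
  set.seed(3)
  tru <- cumsum(runif(50, 0.7, 1.1))
  j <- ensemble_rpeaks(list(mk(tru + runif(50, -0.03, 0.03), "a"),
                            mk(tru + runif(50, -0.03, 0.03), "b")))
  expect_true(all(abs(j$peak_times_s - tru) <= 0.03 + 1e-9))
})

test_that("heart rate is 60/RR after implausible-beat rejection", {
  expect_equal(heart_rate(seq(0, 30, by = 1))$bpm, rep(60, 30))
  expect_equal(heart_rate(seq(0, 30, by = 0.5))$bpm, rep(120, 60))
  expect_equal(nrow(heart_rate(c(5))), 0L)
  # an ectopic-like extra peak is rejected by the RR filters
  t <- seq(0, 30, by = 1)
  bad <- sort(c(t, 10.05))
  hr <- heart_rate(bad)
  expect_true(all(hr$bpm < 130))
})

test_that("annotation extension clamps, merges, and composes", {
  ev <- data.frame(start_s = 100, end_s = 160)
  expect_equal(extend_annotations(ev, 30, 30, 1000),
               data.frame(start_s = 70, end_s = 190))
  expect_equal(extend_annotations(data.frame(start_s = 10, end_s = 20),
                                  30, 30, 1000),
               data.frame(start_s = 0, end_s = 50))
  two <- data.frame(start_s = c(100, 200), end_s = c(160, 260))
  expect_equal(extend_annotations(two, 30, 30, 1000),
               data.frame(start_s = 70, end_s = 290))
  # extending twice equals extending once by the doubled margin
  set.seed(4)
  s <- sort(runif(5, 50, 900)); e <- s + runif(5, 5, 60)
  ev <- data.frame(start_s = s, end_s = e)
  expect_equal(extend_annotations(extend_annotations(ev, 30, 30, 1000),
                                  30, 30, 1000),
               extend_annotations(ev, 60, 60, 1000))
})

test_that("heart-rate features match a brute-force recomputation", {
  flat <- hr_series_for_test(60, 180)
  g <- make_grid(180, 1, 60, 10)
  Fm <- extract_hr_features(flat, g)
  expect_equal(unname(Fm[1, c("slope_hr", "rmssd", "baseline_ratio")]),
               c(0, 0, 1))
  # linear 60 -> 90 BPM across one 60 s window: slope (90-60)/60
  ramp <- hr_series_for_test(60, 60)
  ramp$bpm <- 60 + 0.5 * ramp$times_s
  g1 <- make_grid(60, 1, 60, 10)
  expect_equal(unname(extract_hr_features(ramp, g1)[1, "slope_hr"]), 0.5,
               tolerance = 1e-6)
  # randomized series against a per-window direct recomputation
  set.seed(9)
  hr <- hr_series_for_test(70, 300)
  hr$bpm <- 70 + cumsum(rnorm(300, sd = 0.5))
  g3 <- make_grid(300, 1, 60, 10)
  Fm3 <- extract_hr_features(hr, g3)
  for (i in sample(seq_along(g3$starts), 5)) {
    a <- g3$starts[i]
    sel <- hr$times_s >= a & hr$times_s < a + 60
    bpm <- hr$bpm[sel]
    expect_equal(unname(Fm3[i, "mean_hr"]), mean(bpm))
    expect_equal(unname(Fm3[i, "range_hr"]), max(bpm) - min(bpm))
    expect_equal(unname(Fm3[i, "rr_sd"]), sd(60 / bpm))
    expect_equal(unname(Fm3[i, "rmssd"]), sqrt(mean(diff(60 / bpm)^2)))
    expect_equal(unname(Fm3[i, "pnn50"]), mean(abs(diff(60 / bpm)) > 0.05))
  }
  # sparse windows are flagged missing
  sparse <- data.frame(times_s = c(1, 2, 3), bpm = c(60, 60, 60))
  class(sparse) <- class(hr)
  expect_false(any(attr(extract_hr_features(sparse, g1), "valid")))
})

test_that("ECG events span full 60 s windows merged on overlap", {
  g <- make_grid(600, 1, 60, 10)
  pos <- g$starts == 100
  expect_equal(form_ecg_events(pos, g)[, c("start_s", "end_s")],
               data.frame(start_s = 100, end_s = 160))
  pos2 <- g$starts %in% c(100, 110)
  expect_equal(form_ecg_events(pos2, g)[, c("start_s", "end_s")],
               data.frame(start_s = 100, end_s = 170))
  expect_equal(nrow(form_ecg_events(rep(FALSE, length(g$starts)), g)), 0L)
  # durations >= 60 s and multiples of the 10 s hop
  set.seed(10)
  for (i in 1:50) {
    ev <- form_ecg_events(rbinom(length(g$starts), 1, 0.2), g)
    d <- ev$end_s - ev$start_s
    expect_true(all(d >= 60) && all(d %% 10 == 0))
  }
})

test_that("tachycardia status follows the 20 BPM responder criterion", {
  base <- hr_series_for_test(70, 400)
  sz <- data.frame(start_s = 200, end_s = 240)
  mk <- function(peak) {
    h <- base
    h$bpm[h$times_s >= 200 & h$times_s < 240] <- peak
    h
  }
  expect_equal(classify_tachy_response(mk(95), sz)$status, "responder")
  expect_equal(classify_tachy_response(mk(80), sz)$status, "intermediate")
  expect_equal(classify_tachy_response(mk(70), sz)$status, "nonresponder")
  expect_equal(classify_tachy_response(mk(95), sz)$hr_increase_bpm, 25)
  # no pre-ictal coverage -> undetermined
  early <- data.frame(start_s = 0.5, end_s = 20)
  expect_equal(classify_tachy_response(base, early)$status, "undetermined")
})

test_that("ECG classifier separates responder seizures and stays silent on
          non-responders", {
  cohort <- gen_cohort(n = 3, seed = 50, duration_s = 600,
                       ictal_hr_increase = 25)
  g <- make_grid(600, 1, 60, 10)
  feats <- list(); labs <- list()
  for (el in cohort) {
    hr <- derive_hr(el)
    Fm <- extract_hr_features(hr, g)
    v <- attr(Fm, "valid")
    ext <- extend_annotations(el$annotations, 30, 30, 600)
    y <- label_windows(g, data.frame(start_s = ext$start_s,
                                     end_s = ext$end_s))
    feats[[length(feats) + 1]] <- Fm[v, , drop = FALSE]
    labs[[length(labs) + 1]] <- y[v]
  }
  m <- train_ecg_classifier(do.call(rbind, feats), unlist(labs))
  det <- 0; tot <- 0
  for (el in cohort) {
    mt <- match_events(detect_ecg(el$recording, m), el$annotations, 600)
    det <- det + mt$detected_seizures
    tot <- tot + mt$detected_seizures + mt$missed_seizures
  }
  expect_gte(det / tot, 0.8)
  nr <- gen_recording(simulation_config(duration_s = 600,
                                        ictal_hr_increase = 0, seed = 99))
  expect_equal(nrow(detect_ecg(nr$recording, m)), 0L)
  expect_error(train_ecg_classifier(feats[[1]],
                                    rep(FALSE, nrow(feats[[1]]))),
               "single class")
})
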