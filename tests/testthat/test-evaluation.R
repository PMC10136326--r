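test_that("event matching counts overlap-based TPs, FPs and misses", {
  truth <- data.frame(start_s = 100, end_s = 160)
  m <- match_events(data.frame(start_s = 110, end_s = 130), truth, 1000)
  expect_equal(unlist(m[c("tp_detections", "fp_detections",
                          "detected_seizures", "missed_seizures")]),
               c(tp_detections = 1, fp_detections = 0,
                 detected_seizures = 1, missed_seizures = 0))
  # multiple detections of one seizure inflate TP over the seizure count
  m2 <- match_events(data.frame(start_s = c(105, 140), end_s = c(120, 155)),
                     truth, 1000)
  expect_equal(m2$tp_detections, 2)
  expect_equal(m2$detected_seizures, 1)
  m3 <- match_events(data.frame(start_s = 200, end_s = 260), truth, 1000)
  expect_equal(c(m3$tp_detections, m3$fp_detections, m3$missed_seizures),
               c(0, 1, 1))
  expect_error(match_events(truth, truth, 0), "positive")
})

test_that("event matching agrees with the all-pairs oracle", {
  set.seed(13)
  for (i in 1:1000) {
    alarms <- random_events(sample(0:6, 1), 7200)
    truth <- random_events(sample(0:5, 1), 7200)
    got <- match_events(alarms, truth, 7200)
    want <- naive_match(alarms, truth, 7200)
    expect_equal(got$tp_detections, want$tp)
    expect_equal(got$fp_detections, want$fp)
    expect_equal(got$detected_seizures, want$detected)
    expect_equal(got$missed_seizures, want$missed)
  }
})

test_that("metrics implement the four definitions with flagged 0/0 cases", {
  mk <- function(tp, fp, det, mis, dur)
    structure(list(tp_detections = tp, fp_detections = fp,
                   detected_seizures = det, missed_seizures = mis,
                   duration_s = dur), class = "ws_match")
  s <- compute_metrics(mk(5, 10, 4, 1, 86400))
  expect_equal(s$sensitivity, 0.8)
  expect_equal(s$fd_per_24h, 10)             # one day of recording
  expect_equal(s$ppv, 5 / 15)
  expect_equal(s$f1, 2 * 0.8 * (1 / 3) / (0.8 + 1 / 3))
  # FD/24h is linear in FP and inversely proportional to duration
  expect_equal(compute_metrics(mk(0, 20, 0, 1, 86400))$fd_per_24h, 20)
  expect_equal(compute_metrics(mk(0, 10, 0, 1, 2 * 86400))$fd_per_24h, 5)
  # 0/0 ratios are flagged, never silently zero
  u <- compute_metrics(mk(0, 0, 0, 1, 1000))
  expect_true(is.na(u$ppv))
  expect_true("ppv" %in% u$undefined)
  # F1 collapses to 0 when sensitivity is 0 but PPV is defined
  z <- compute_metrics(mk(0, 3, 0, 2, 1000))
  expect_equal(z$f1, 0)
  expect_equal(f1_score(0.5, 0), 0)
})

test_that("reader scoring ignores the algorithm's own misses", {
  truth <- data.frame(start_s = c(100, 300, 500), end_s = c(160, 360, 560))
  alarms <- data.frame(alarm_id = c("a1", "a2", "a3"),
                       start_s = c(110, 320, 700),
                       end_s = c(130, 340, 760))
  # seizure at 500 has no alarm: excluded from every reader count
  perfect <- data.frame(alarm_id = c("a1", "a2", "a3"),
                        label = c("seizure", "seizure", "artifact"))
  s <- score_reader(perfect, alarms, truth, 86400)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$fp_detections, 0)
  # labelling the non-overlapping alarm "seizure" adds an FP
  optimist <- data.frame(alarm_id = c("a1", "a2", "a3"),
                         label = c("seizure", "artifact", "seizure"))
  s2 <- score_reader(optimist, alarms, truth, 86400)
  expect_equal(s2$fp_detections, 1)
  expect_equal(s2$missed_seizures, 1)        # a2 overlaps but wasn't "seizure"
  expect_error(score_reader(data.frame(alarm_id = "zz", label = "seizure"),
                            alarms, truth, 86400), "unknown alarm")
  expect_error(score_reader(data.frame(alarm_id = "a1", label = "noise"),
                            alarms, truth, 86400), "label")
  # an all-"seizure" reader reproduces the algorithm's own TP/FP counts
  all_sz <- data.frame(alarm_id = alarms$alarm_id, label = "seizure")
  s3 <- score_reader(all_sz, alarms, truth, 86400)
  alg <- match_events(alarms, truth, 86400)
  expect_equal(s3$tp_detections, alg$tp_detections)
  expect_equal(s3$fp_detections, alg$fp_detections)
})

test_that("stratified scores partition the global counts", {
  set.seed(14)
  per_rec <- lapply(1:6, function(i) {
    truth <- random_events(2, 3600)
    alarms <- random_events(3, 3600)
    list(alarms = alarms, truth = truth, duration_s = 3600,
         strata = list(tachy = c("responder", "nonresponder")[1 + i %% 2]))
  })
  out <- stratify_scores(per_rec, by = "tachy")
  expect_setequal(names(out), c("responder", "nonresponder"))
  tot <- function(f) sum(vapply(out, `[[`, numeric(1), f))
  pooled <- lapply(per_rec, function(el)
    match_events(el$alarms, el$truth, el$duration_s))
  expect_equal(tot("tp_detections"),
               sum(vapply(pooled, `[[`, numeric(1), "tp_detections")))
  expect_equal(tot("detected_seizures") + tot("missed_seizures"), 12)
  # per-stratum sensitivity equals a direct per-subset recomputation
  for (lev in names(out)) {
    sel <- Filter(function(el) el$strata$tachy == lev, per_rec)
    ms <- lapply(sel, function(el)
      match_events(el$alarms, el$truth, el$duration_s))
    det <- sum(vapply(ms, `[[`, numeric(1), "detected_seizures"))
    mis <- sum(vapply(ms, `[[`, numeric(1), "missed_seizures"))
    expect_equal(out[[lev]]$sensitivity, det / (det + mis))
  }
})

test_that("Cohen's kappa matches the agreement-table formula", {
  expect_equal(cohen_kappa(c("s", "a", "s", "o"), c("s", "a", "s", "o")), 1)
  # a=20 both-yes, b=5, c=10 discordant, d=15 both-no: kappa = 0.4
  a <- c(rep("y", 20), rep("y", 5), rep("n", 10), rep("n", 15))
  b <- c(rep("y", 20), rep("n", 5), rep("y", 10), rep("n", 15))
  expect_equal(cohen_kappa(a, b), 0.4)
  expect_equal(cohen_kappa(a, b), kappa_from_table(20, 5, 10, 15))
  # random 2x2 tables against the algebraic oracle
  set.seed(15)
  for (i in 1:50) {
    tb <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    x <- rep(c("y", "y", "n", "n"), tb)
    y <- rep(c("y", "n", "y", "n"), tb)
    expect_equal(cohen_kappa(x, y),
                 kappa_from_table(tb[1], tb[2], tb[3], tb[4]))
  }
  # marginal-preserving shuffle drives kappa to ~0
  set.seed(16)
  x <- sample(c("y", "n"), 4000, TRUE, prob = c(0.3, 0.7))
  expect_lt(abs(cohen_kappa(x, sample(x))), 0.08)
  expect_error(cohen_kappa(c("a", "b"), c("a")), "length")
  # raters constant on different categories: p_e = 0, kappa = 0
  expect_equal(cohen_kappa(c("a", "a"), c("b", "b")), 0)
})

test_that("McNemar's test uses the exact branch for small discordant counts", {
  expect_equal(mcnemar_counts(7, 7)$p_value, 1)
  expect_equal(mcnemar_counts(10, 0)$p_value, 2 * 0.5^10)
  d <- mcnemar_counts(0, 0)
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  expect_error(mcnemar_counts(-1, 3), "non-negative")
  # large counts: continuity-corrected chi-squared
  big <- mcnemar_counts(40, 20)
  expect_equal(big$method, "chi-squared")
  expect_equal(big$statistic, (abs(40 - 20) - 1)^2 / 60)
  expect_equal(discordant_counts(c(TRUE, TRUE, FALSE, FALSE),
                                 c(TRUE, FALSE, TRUE, FALSE)),
               list(b = 1L, c = 1L))
})
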