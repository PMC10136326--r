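# ECG detector: R-peak ensemble, heart-rate derivation with artifact
# rejection, 60 s / 10 s heart-rate features, classification against
# +/-30 s extended training labels, >= 60 s event formation, and the
# ictal-tachycardia responder classification.

#' Detect R-peaks in a single-lead ECG
#'
#' Two independent implementations are available: a derivative-threshold
#' detector in the Pan-Tompkins tradition (band-pass 5-15 Hz, derivative,
#' squaring, 150 ms moving-window integration, adaptive threshold) and an
#' amplitude-adaptive local-maximum detector (baseline removal by running
#' median, per-chunk adaptive threshold). Both refine candidates to the
#' local maximum of the band-passed signal and enforce a 250 ms refractory
#' period.
#'
#' @param ecg Numeric ECG samples, mV.
#' @param fs Sampling rate, Hz (>= 100).
#' @param method `"pan_tompkins"` or `"local_max"`.
#' @return A `ws_rpeaks`: list with `peak_times_s` (strictly increasing
#'   seconds) and `detector_id`. A flat signal yields an empty set with a
#'   warning.
#' @export
detect_rpeaks <- function(ecg, fs, method = c("pan_tompkins", "local_max")) {
  method <- match.arg(method)
  stopifnot(fs >= 100)
  if (length(ecg) < 10 * fs) stop("need at least 10 s of ECG")
  if (stats::sd(ecg) < 1e-6) {
    warning("flat ECG signal; no R-peaks detected")
    return(structure(list(peak_times_s = numeric(0), detector_id = method),
                     class = "ws_rpeaks"))
  }
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- as.numeric(signal::filtfilt(bf, ecg))
  refr <- as.integer(round(0.25 * fs))

  if (method == "pan_tompkins") {
    dx <- c(0, diff(xb))
    sq <- dx^2
    k <- as.integer(round(0.15 * fs))
    mwi <- as.numeric(stats::filter(sq, rep(1 / k, k), sides = 2))
    mwi[!is.finite(mwi)] <- 0
    feat <- mwi
  } else {
    base <- stats::runmed(ecg, k = 2L * as.integer(round(0.3 * fs)) + 1L)
    feat <- pmax(ecg - base, 0)^2
  }

  # adaptive threshold per ~10 s chunk against that chunk's peak level
  n <- length(feat)
  chunk <- as.integer(round(10 * fs))
  thr <- numeric(n)
  for (a in seq(1L, n, by = chunk)) {
    b <- min(n, a + chunk - 1L)
    thr[a:b] <- 0.2 * max(feat[a:b])
  }
  cand <- which(feat > thr &
                  feat >= c(-Inf, feat[-n]) & feat >= c(feat[-1L], -Inf))
  if (!length(cand)) {
    warning("no QRS-like activity found")
    return(structure(list(peak_times_s = numeric(0), detector_id = method),
                     class = "ws_rpeaks"))
  }
  # refine each candidate to the band-passed maximum nearby, then apply the
  # refractory period keeping the larger peak
  half <- as.integer(round(0.1 * fs))
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(xb[lo:hi]) - 1L
  }, integer(1))
  o <- order(xb[ref], decreasing = TRUE)
  keep <- logical(0)
  taken <- integer(0)
  for (i in ref[o]) {
    if (!length(taken) || all(abs(taken - i) > refr)) taken <- c(taken, i)
  }
  taken <- sort(unique(taken))
  structure(list(peak_times_s = (taken - 1L) / fs, detector_id = method),
            class = "ws_rpeaks")
}

#' Majority-vote ensemble of R-peak sets
#'
#' Pools the peaks of all detectors, clusters them greedily within `tol_s`,
#' and keeps the centroid of every cluster supported by a strict majority of
#' detectors.
#'
#' @param peak_sets List of `ws_rpeaks` (at least 2; a single set is passed
#'   through with a warning).
#' @param tol_s Clustering tolerance, seconds.
#' @return A `ws_rpeaks` with `detector_id = "ensemble"`.
#' @export
ensemble_rpeaks <- function(peak_sets, tol_s = 0.1) {
  if (length(peak_sets) < 2L) {
    warning("single R-peak detector; ensemble is a passthrough")
    out <- peak_sets[[1L]]
    out$detector_id <- "ensemble"
    return(out)
  }
  times <- unlist(lapply(peak_sets, `[[`, "peak_times_s"))
  ids <- rep(seq_along(peak_sets),
             vapply(peak_sets, function(p) length(p$peak_times_s), integer(1)))
  if (!length(times))
    return(structure(list(peak_times_s = numeric(0),
                          detector_id = "ensemble"), class = "ws_rpeaks"))
  o <- order(times)
  times <- times[o]; ids <- ids[o]
  cl <- cumsum(c(1L, diff(times) > tol_s))
  need <- floor(length(peak_sets) / 2) + 1L
  cent <- tapply(times, cl, mean)
  nsup <- tapply(ids, cl, function(v) length(unique(v)))
  structure(list(peak_times_s = as.numeric(cent[nsup >= need]),
                 detector_id = "ensemble"), class = "ws_rpeaks")
}

#' Instantaneous heart rate from R-peaks
#'
#' Physiologically implausible beats are removed first: R-R intervals
#' outside 0.24-3 s or with a beat-to-beat change above 35% are discarded.
#' Each remaining interval contributes HR = 60/RR at its midpoint; an
#' optional running-median smoother (over `smooth_beats` beats) suppresses
#' residual detection jitter.
#'
#' @param peaks A `ws_rpeaks` (or numeric vector of peak times, seconds).
#' @param rr_range Plausible R-R range, seconds.
#' @param max_rel_jump Maximum relative beat-to-beat R-R change.
#' @param smooth_beats Odd window width of the median smoother (0 = none).
#' @return A `ws_hr_series` data frame (`times_s`, `bpm`); empty when fewer
#'   than 2 peaks survive.
#' @export
heart_rate <- function(peaks, rr_range = c(0.24, 3), max_rel_jump = 0.35,
                       smooth_beats = 0L) {
  t <- if (inherits(peaks, "ws_rpeaks")) peaks$peak_times_s else
    as.numeric(peaks)
  if (length(t) < 2L) return(hr_series(numeric(0), numeric(0)))
  rr <- diff(t)
  mid <- (t[-length(t)] + t[-1L]) / 2
  ok <- rr >= rr_range[1L] & rr <= rr_range[2L]
  prev <- c(NA, rr[-length(rr)])
  jump <- abs(rr - prev) / prev
  ok <- ok & (is.na(jump) | jump <= max_rel_jump)
  rr <- rr[ok]; mid <- mid[ok]
  bpm <- 60 / rr
  keep <- bpm > 20 & bpm < 250
  bpm <- bpm[keep]; mid <- mid[keep]
  if (smooth_beats >= 3L && length(bpm) >= smooth_beats)
    bpm <- stats::runmed(bpm, k = 2L * (smooth_beats %/% 2L) + 1L)
  hr_series(mid, bpm)
}

#' Extend seizure annotations in time
#'
#' Training labels for the ECG classifier are widened by 30 s before and
#' after each seizure (the autonomic signature is slower than the EEG one);
#' extended intervals are clamped to the recording and merged when they
#' overlap.
#'
#' @param events Annotation data frame (`start_s`, `end_s`).
#' @param pre_s,post_s Extension, seconds.
#' @param duration_s Recording duration for clamping.
#' @return Data frame of merged extended intervals.
#' @export
extend_annotations <- function(events, pre_s = 30, post_s = 30, duration_s) {
  if (nrow(events) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  merge_intervals(pmax(0, events$start_s - pre_s),
                  pmin(duration_s, events$end_s + post_s))
}

hr_feature_names <- function()
  c("mean_hr", "range_hr", "slope_hr", "rr_sd", "rmssd", "pnn50",
    "baseline_ratio")

#' Heart-rate features on the 60 s / 10 s grid
#'
#' Seven features per window: mean HR, max-min HR, least-squares HR slope
#' (BPM/s), SD of the R-R intervals, RMSSD, pNN50, and the ratio of the
#' window-mean HR to a trailing 5-minute baseline. Windows containing fewer
#' than 5 beats are flagged missing (attribute `valid`) and excluded from
#' classification.
#'
#' @param hr A `ws_hr_series`.
#' @param grid A `ws_grid` (60 s windows, 10 s hop for the detector).
#' @return Matrix `n_windows x 7` with attribute `valid` (logical).
#' @export
extract_hr_features <- function(hr, grid) {
  stopifnot(inherits(grid, "ws_grid"))
  n <- length(grid$starts)
  out <- matrix(NA_real_, n, 7L, dimnames = list(NULL, hr_feature_names()))
  valid <- logical(n)
  for (i in seq_len(n)) {
    a <- grid$starts[i]; b <- a + grid$win_s
    sel <- hr$times_s >= a & hr$times_s < b
    if (sum(sel) < 5L) next
    tt <- hr$times_s[sel]; bpm <- hr$bpm[sel]
    rr <- 60 / bpm
    drr <- diff(rr)
    tc <- tt - mean(tt)
    slope <- if (sum(tc^2) > 0) sum(tc * (bpm - mean(bpm))) / sum(tc^2) else 0
    base_sel <- hr$times_s >= max(0, a - 300) & hr$times_s < a
    base <- if (sum(base_sel) >= 5L) mean(hr$bpm[base_sel]) else {
      pre <- hr$bpm[hr$times_s < a]
      if (length(pre) >= 5L) mean(pre) else mean(bpm)
    }
    out[i, ] <- c(mean(bpm), max(bpm) - min(bpm), slope, stats::sd(rr),
                  if (length(drr)) sqrt(mean(drr^2)) else 0,
                  if (length(drr)) mean(abs(drr) > 0.05) else 0,
                  mean(bpm) / base)
    valid[i] <- TRUE
  }
  attr(out, "valid") <- valid
  out
}

#' Train the ECG window classifier
#'
#' Same contract as [train_eeg_classifier()] (standardization bundled with
#' an RBF-SVM, inverse-frequency class weights), fitted on heart-rate
#' features against the +/-30 s extended seizure labels.
#'
#' @param features Matrix from [extract_hr_features()] (invalid windows
#'   removed by the caller or via the `valid` attribute).
#' @param labels Logical window labels from the extended annotations.
#' @param cost,gamma SVM hyperparameters.
#' @return A `ws_classifier`.
#' @export
train_ecg_classifier <- function(features, labels, cost = 1, gamma = NULL)
  train_window_classifier(features, labels, cost = cost, gamma = gamma)

#' Form ECG detection events from window labels
#'
#' Every positive 60 s window contributes its full span; overlapping or
#' contiguous spans are merged, so events last at least 60 s and grow in
#' 10 s steps.
#'
#' @param positives Logical vector aligned to the grid.
#' @param grid A `ws_grid` with `win_s = 60`, `hop_s = 10`.
#' @param scores Optional decision values (mean per event is reported).
#' @return Event data frame (`start_s`, `end_s`, `modality = "ecg"`,
#'   `score`).
#' @export
form_ecg_events <- function(positives, grid, scores = NULL) {
  idx <- which(as.logical(positives))
  if (!length(idx)) return(empty_events("ecg"))
  spans <- merge_intervals(grid$starts[idx], grid$starts[idx] + grid$win_s)
  sc <- rep(NA_real_, nrow(spans))
  if (!is.null(scores)) {
    for (i in seq_len(nrow(spans))) {
      w <- idx[grid$starts[idx] >= spans$start_s[i] - 1e-9 &
                 grid$starts[idx] < spans$end_s[i]]
      sc[i] <- mean(scores[w])
    }
  }
  data.frame(start_s = spans$start_s, end_s = spans$end_s,
             modality = "ecg", score = sc, stringsAsFactors = FALSE)
}

#' Classify the ictal heart-rate response of seizures
#'
#' For each seizure the increase is the maximum heart rate inside
#' `[start, end + 30 s]` minus the median heart rate in the
#' `baseline_win_s` seconds before onset. An increase of at least 20 BPM is
#' a responder, an increase in (0, 20) BPM an intermediate response, and no
#' increase (<= 0) a non-responder.
#'
#' @param hr A `ws_hr_series`.
#' @param seizure_events Data frame with `start_s`, `end_s`.
#' @param baseline_win_s Pre-ictal baseline window, seconds.
#' @return Data frame with `start_s`, `end_s`, `hr_increase_bpm`, `status`
#'   (`responder` / `intermediate` / `nonresponder`, or `undetermined` when
#'   the pre-ictal window has insufficient heart-rate coverage).
#' @export
classify_tachy_response <- function(hr, seizure_events, baseline_win_s = 60) {
  n <- nrow(seizure_events)
  inc <- rep(NA_real_, n)
  status <- rep("undetermined", n)
  for (i in seq_len(n)) {
    a <- seizure_events$start_s[i]; b <- seizure_events$end_s[i]
    pre <- hr$bpm[hr$times_s >= a - baseline_win_s & hr$times_s < a]
    ict <- hr$bpm[hr$times_s >= a & hr$times_s <= b + 30]
    if (length(pre) < 3L || length(ict) < 1L) next
    inc[i] <- max(ict) - stats::median(pre)
    status[i] <- if (inc[i] >= 20) "responder"
      else if (inc[i] > 0) "intermediate" else "nonresponder"
  }
  data.frame(start_s = seizure_events$start_s,
             end_s = seizure_events$end_s,
             hr_increase_bpm = inc, status = status,
             stringsAsFactors = FALSE)
}

#' Run the full ECG detector on a recording
#'
#' R-peak ensemble (both built-in detectors), heart-rate derivation with
#' artifact rejection and a light median smoother, 60 s / 10 s heart-rate
#' features, classification, and >= 60 s event formation.
#'
#' @param recording A `ws_recording` with an `ecg` channel.
#' @param model A `ws_classifier` from [train_ecg_classifier()].
#' @param threshold Decision threshold (default 0).
#' @return Event data frame (`start_s`, `end_s`, `modality`, `score`).
#' @export
detect_ecg <- function(recording, model, threshold = 0) {
  ch <- recording_channel(recording, "ecg")
  pk <- ensemble_rpeaks(list(
    detect_rpeaks(ch$samples, ch$fs, "pan_tompkins"),
    detect_rpeaks(ch$samples, ch$fs, "local_max")))
  hr <- heart_rate(pk, smooth_beats = 5L)
  grid <- make_grid(as.integer(round(recording$duration_s)), 1,
                    win_s = 60, hop_s = 10)
  feats <- extract_hr_features(hr, grid)
  valid <- attr(feats, "valid")
  pos <- logical(length(grid$starts))
  sc <- rep(NA_real_, length(grid$starts))
  if (any(valid)) {
    pr <- predict(model, feats[valid, , drop = FALSE],
                  threshold = threshold)
    pos[valid] <- pr$positive
    sc[valid] <- pr$decision
  }
  form_ecg_events(pos, grid, scores = sc)
}
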