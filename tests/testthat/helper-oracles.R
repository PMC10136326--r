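# Independent oracles and small fixture builders used across the suite.

# Naive 8-of-10 post-processing oracle: enumerate every group, mark the
# seconds its span covers on a boolean timeline, and read events off the
# runs. Deliberately unrelated to the package's cumulative-sum route.
naive_postprocess <- function(x, group_len = 10L, min_pos = 8L, hop = 1) {
  x <- as.integer(as.logical(x))
  n <- length(x)
  if (n < group_len)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  cover <- rep(FALSE, n - 1L + group_len)   # unit-hop slots 0 .. n-2+k
  for (g in 0:(n - group_len)) {
    if (sum(x[(g + 1L):(g + group_len)]) >= min_pos)
      cover[(g + 1L):(g + group_len)] <- TRUE
  }
  r <- rle(cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start_s = starts[keep] * hop, end_s = ends[keep] * hop)
}

# All-pairs brute-force event matcher (O(n*m) double loop).
naive_match <- function(alarms, truth, duration_s) {
  ov <- function(a1, b1, a2, b2) a1 < b2 && a2 < b1
  a_hit <- rep(FALSE, nrow(alarms))
  s_hit <- rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(alarms))) {
    for (j in seq_len(nrow(truth))) {
      if (ov(alarms$start_s[i], alarms$end_s[i],
             truth$start_s[j], truth$end_s[j])) {
        a_hit[i] <- TRUE; s_hit[j] <- TRUE
      }
    }
  }
  list(tp = sum(a_hit), fp = sum(!a_hit),
       detected = sum(s_hit), missed = sum(!s_hit))
}

# Cohen's kappa straight from a 2x2 agreement table (algebraic form).
kappa_from_table <- function(a, b, c, d) {
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# Random non-overlapping event set on [0, dur)
random_events <- function(n, dur, max_len = 60) {
  if (n == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  repeat {
    s <- sort(runif(n, 0, dur - max_len))
    e <- s + runif(n, 1, max_len)
    if (all(s[-1] >= e[-n]) || n == 1)
      return(data.frame(start_s = s, end_s = pmin(e, dur)))
  }
}

# F1 of detected vs true peak times at a matching tolerance
peak_f1 <- function(det, tru, tol = 0.05) {
  if (!length(det) || !length(tru)) return(0)
  used <- logical(length(tru)); tp <- 0L
  for (d in det) {
    j <- which(!used & abs(tru - d) <= tol)
    if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L }
  }
  prec <- tp / length(det); rec <- tp / length(tru)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# constant-rate heart-rate series (1 Hz sampling) for ECG synthesis tests
hr_series_for_test <- function(bpm, duration_s) {
  df <- data.frame(times_s = seq(0, duration_s - 1), bpm = bpm)
  class(df) <- c("ws_hr_series", "data.frame")
  df
}

# derived heart-rate series from a generated recording's ECG channel
derive_hr <- function(sim, smooth_beats = 5L) {
  ecg <- recording_channel(sim$recording, "ecg")
  en <- ensemble_rpeaks(list(
    detect_rpeaks(ecg$samples, ecg$fs, "pan_tompkins"),
    detect_rpeaks(ecg$samples, ecg$fs, "local_max")))
  heart_rate(en, smooth_beats = smooth_beats)
}
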