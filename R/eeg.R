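# bte-EEG detector: 0.5-35 Hz band-pass, 2 s / 1 s sliding windows, a
# 67-feature description of the two channels, an RBF-SVM window classifier,
# and 8-of-10 post-processing into alarm events of at least 10 s.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), matching
#' the 0.5 Hz high-pass / 35 Hz low-pass conditioning used for review of
#' wearable EEG. DC is removed by the high-pass edge.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz; must exceed twice the upper edge.
#' @param low,high Band edges, Hz.
#' @return Filtered signal, same length.
#' @export
eeg_bandpass <- function(x, fs, low = 0.5, high = 35) {
  if (fs <= 2 * high)
    stop("sampling rate ", fs, " Hz must exceed twice the upper band edge (",
         2 * high, " Hz)")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Build a sliding-window grid
#'
#' Windows cover `[start, start + win_s)` with starts at multiples of
#' `hop_s`; the last window must lie fully inside the recording.
#'
#' @param n_samples Number of samples in the signal.
#' @param fs Sampling rate, Hz.
#' @param win_s Window length, seconds (EEG default 2; ECG features use 60).
#' @param hop_s Hop between window starts, seconds (EEG 1; ECG 10).
#' @return A `ws_grid`: list with `win_s`, `hop_s`, `starts` (seconds),
#'   `fs`, `n_samples`.
#' @export
make_grid <- function(n_samples, fs, win_s = 2, hop_s = 1) {
  stopifnot(hop_s <= win_s, hop_s > 0, fs > 0)
  duration <- n_samples / fs
  if (n_samples < win_s * fs)
    stop("recording (", signif(duration, 4), " s) is shorter than one ",
         win_s, " s window")
  n_win <- floor((duration - win_s) / hop_s + 1e-9) + 1L
  structure(list(win_s = win_s, hop_s = hop_s,
                 starts = (seq_len(n_win) - 1L) * hop_s,
                 fs = fs, n_samples = n_samples),
            class = "ws_grid")
}

#' The 67-feature catalogue of the bte-EEG window description
#'
#' 24 time-domain features (12 per channel), 16 frequency-domain (8 per
#' channel), 8 entropy-derived (4 per channel) and 19 cross-channel
#' asymmetry features, for 67 in total. `scale_invariant` marks the subset
#' unchanged when both channels are rescaled by a common positive factor.
#'
#' @return Data frame with columns `name`, `family`, `scale_invariant`.
#' @export
eeg_feature_names <- function() {
  time_f <- c("mean_abs", "rms", "sd", "ptp", "line_length",
              "zero_crossings", "skewness", "kurtosis", "hjorth_activity",
              "hjorth_mobility", "hjorth_complexity", "nonlinear_energy")
  freq_f <- c("relpow_delta", "relpow_theta", "relpow_alpha", "relpow_beta",
              "log_total_power", "spectral_edge95", "peak_freq",
              "spectral_centroid")
  ent_f  <- c("spectral_entropy", "sample_entropy", "perm_entropy",
              "amp_entropy")
  asym_f <- c("logratio_delta", "logratio_theta", "logratio_alpha",
              "logratio_beta", "normdiff_delta", "normdiff_theta",
              "normdiff_alpha", "normdiff_beta", "logratio_total_power",
              "logratio_rms", "logratio_line_length", "diff_zero_crossings",
              "diff_hjorth_mobility", "diff_hjorth_complexity", "corr",
              "xcorr_max", "xcorr_lag_s", "diff_spectral_edge95",
              "diff_peak_freq")
  per_chan <- function(pfx) data.frame(
    name = paste0(pfx, c(time_f, freq_f, ent_f)),
    family = rep(c("time", "frequency", "entropy"), c(12L, 8L, 4L)),
    scale_invariant = c(
      # time: only rate/shape measures survive rescaling
      c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
        TRUE, FALSE),
      # frequency: relative powers and spectral locations do; total power not
      c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
      # entropies are normalized / tolerance-relative
      c(TRUE, TRUE, TRUE, TRUE)),
    stringsAsFactors = FALSE)
  asym <- data.frame(
    name = paste0("asym_", asym_f),
    family = "asymmetry",
    # ratios, normalized differences and correlations are invariant; the
    # difference features compare already-invariant per-channel quantities
    scale_invariant = TRUE,
    stringsAsFactors = FALSE)
  rbind(per_chan("ch1_"), per_chan("ch2_"), asym)
}

# ---- internal per-window computations ------------------------------------

row_max <- function(W) do.call(pmax, lapply(seq_len(ncol(W)), function(j) W[, j]))
row_min <- function(W) do.call(pmin, lapply(seq_len(ncol(W)), function(j) W[, j]))

# sample entropy (m = 2, r = 0.2 sd), computed on the window decimated by 2:
# at wearable sampling rates neighbouring samples are strongly correlated and
# the lag-1 m = 2 embedding saturates, so the decimated estimate is both more
# discriminative and cheaper.
sampen_window <- function(v) {
  v <- v[seq(1L, length(v), by = 2L)]
  n <- length(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(0)
  r <- 0.2 * s
  A <- abs(outer(v, v, "-"))
  Dm <- pmax(A[-n, -n], A[-1L, -1L])
  B <- (sum(Dm < r) - (n - 1L)) / 2
  Dm1 <- pmax(Dm[-(n - 1L), -(n - 1L)], A[-c(1L, 2L), -c(1L, 2L)])
  Acnt <- (sum(Dm1 < r) - (n - 2L)) / 2
  if (B <= 0) return(0)
  if (Acnt <= 0) return(-log(2 / ((n - 3) * (n - 2))))
  -log(Acnt / B)
}

# per-channel feature block; W is n_windows x L, already band-passed
chan_features <- function(W, fs) {
  n <- nrow(W); L <- ncol(W)
  eps <- 1e-12
  m1 <- rowMeans(W)
  C <- W - m1
  v <- rowMeans(C^2)
  sdv <- sqrt(pmax(v, 0))
  d1 <- W[, -1L, drop = FALSE] - W[, -L, drop = FALSE]
  d2 <- d1[, -1L, drop = FALSE] - d1[, -(L - 1L), drop = FALSE]
  v1 <- rowMeans(d1^2); v2 <- rowMeans(d2^2)
  mobility <- sqrt(v1 / pmax(v, eps))
  complexity <- sqrt(v2 / pmax(v1, eps)) / pmax(mobility, eps)

  tf <- cbind(
    mean_abs = rowMeans(abs(W)),
    rms = sqrt(rowMeans(W^2)),
    sd = sdv,
    ptp = row_max(W) - row_min(W),
    line_length = rowSums(abs(d1)),
    zero_crossings = rowSums(W[, -1L, drop = FALSE] *
                               W[, -L, drop = FALSE] < 0),
    skewness = rowMeans(C^3) / pmax(sdv, eps)^3,
    kurtosis = rowMeans(C^4) / pmax(v, eps)^2,
    hjorth_activity = v,
    hjorth_mobility = mobility,
    hjorth_complexity = complexity,
    nonlinear_energy = rowMeans(W[, 2:(L - 1L), drop = FALSE]^2 -
                                  W[, 1:(L - 2L), drop = FALSE] *
                                  W[, 3:L, drop = FALSE]))

  P <- Mod(stats::mvfft(t(C)))^2          # L x n periodogram (DC removed)
  freqs <- (seq_len(L) - 1L) * fs / L
  band <- function(lo, hi) freqs > lo & freqs <= hi & freqs <= fs / 2
  mask <- band(0.5, 35)
  fm <- freqs[mask]
  Pm <- P[mask, , drop = FALSE]
  total <- colSums(Pm)
  pow <- function(lo, hi) colSums(P[band(lo, hi), , drop = FALSE])
  bp <- cbind(delta = pow(0.5, 4), theta = pow(4, 8),
              alpha = pow(8, 13), beta = pow(13, 35))
  rel <- bp / ifelse(total > 0, total, 1)
  rel[total <= 0, ] <- 0.25                # all-zero window: uniform bands
  cum <- apply(Pm, 2L, cumsum)
  edge_idx <- colSums(cum < 0.95 * rep(total, each = nrow(Pm))) + 1L
  edge <- ifelse(total > 0, fm[pmin(edge_idx, length(fm))], 0)
  pk <- ifelse(total > 0, fm[max.col(t(Pm), ties.method = "first")], 0)
  centroid <- ifelse(total > 0, colSums(fm * Pm) / pmax(total, eps), 0)
  pn <- Pm / rep(pmax(total, eps), each = nrow(Pm))
  spec_ent <- ifelse(total > 0,
                     -colSums(pn * log(pn + 1e-15)) / log(nrow(Pm)), 1)

  ff <- cbind(relpow_delta = rel[, 1L], relpow_theta = rel[, 2L],
              relpow_alpha = rel[, 3L], relpow_beta = rel[, 4L],
              log_total_power = log(total + eps),
              spectral_edge95 = edge, peak_freq = pk,
              spectral_centroid = centroid)

  # permutation entropy, order 3, vectorized over windows
  A1 <- W[, 1:(L - 2L), drop = FALSE]
  A2 <- W[, 2:(L - 1L), drop = FALSE]
  A3 <- W[, 3:L, drop = FALSE]
  code <- (A1 < A2) + 2L * (A2 < A3) + 4L * (A1 < A3)
  pe <- numeric(n)
  for (k in 0:7) {
    pk_ <- rowSums(code == k) / (L - 2L)
    pe <- pe - ifelse(pk_ > 0, pk_ * log(pk_), 0)
  }
  pe <- pe / log(6)

  # amplitude-histogram entropy over 10 bins spanning the window's range
  rng <- row_max(W) - row_min(W)
  U <- (W - row_min(W)) / ifelse(rng > 0, rng, 1)
  bins <- pmin(floor(U * 10), 9L)
  ae <- numeric(n)
  for (k in 0:9) {
    pk_ <- rowSums(bins == k) / L
    ae <- ae - ifelse(pk_ > 0, pk_ * log(pk_), 0)
  }
  ae <- ifelse(rng > 0, ae / log(10), 0)

  se <- vapply(seq_len(n), function(i) sampen_window(W[i, ]), numeric(1))

  ef <- cbind(spectral_entropy = spec_ent, sample_entropy = se,
              perm_entropy = pe, amp_entropy = ae)
  list(feats = cbind(tf, ff, ef), C = C, sd = sdv,
       bp = bp, total = total, tf = tf, edge = edge, pk = pk,
      mobility = mobility, complexity = complexity)
}

#' Extract the 67-feature matrix from two bte-EEG channels
#'
#' @param x1,x2 Cross-head and ipsilateral channel samples (already
#'   band-passed to 0.5-35 Hz), µV.
#' @param fs Sampling rate, Hz.
#' @param grid A `ws_grid` from [make_grid()].
#' @return Numeric matrix `n_windows x 67` with column names from
#'   [eeg_feature_names()]; guaranteed free of non-finite values.
#' @export
extract_eeg_features <- function(x1, x2, fs, grid) {
  stopifnot(inherits(grid, "ws_grid"))
  for (x in list(x1, x2)) {
    bad <- which(!is.finite(x))
    if (length(bad)) {
      tbad <- (bad[1L] - 1L) / fs
      widx <- which(grid$starts <= tbad & tbad < grid$starts + grid$win_s)
      stop("non-finite sample in input at window ",
           if (length(widx)) widx[1L] else NA_integer_)
    }
  }
  L <- as.integer(round(grid$win_s * fs))
  idx0 <- as.integer(round(grid$starts * fs))
  M <- outer(idx0, seq_len(L), "+")
  W1 <- matrix(x1[M], nrow = length(idx0))
  W2 <- matrix(x2[M], nrow = length(idx0))

  c1 <- chan_features(W1, fs)
  c2 <- chan_features(W2, fs)
  eps <- 1e-12

  lr <- function(a, b) log((a + eps) / (b + eps))
  nd <- function(a, b) (a - b) / (a + b + eps)
  r_num <- rowSums(c1$C * c2$C)
  r_den <- sqrt(rowSums(c1$C^2) * rowSums(c2$C^2))
  corr <- ifelse(r_den > 0, r_num / r_den, 0)

  K <- max(1L, as.integer(round(0.05 * fs)))
  lags <- -K:K
  nwin <- nrow(W1)
  XC <- matrix(0, nwin, length(lags))
  den <- pmax(L * c1$sd * c2$sd, eps)
  for (j in seq_along(lags)) {
    l <- lags[j]
    if (l >= 0) {
      XC[, j] <- rowSums(c1$C[, 1:(L - l), drop = FALSE] *
                           c2$C[, (1 + l):L, drop = FALSE]) / den
    } else {
      XC[, j] <- rowSums(c1$C[, (1 - l):L, drop = FALSE] *
                           c2$C[, 1:(L + l), drop = FALSE]) / den
    }
  }
  best <- max.col(abs(XC), ties.method = "first")
  xcorr_max <- abs(XC)[cbind(seq_len(nwin), best)]
  xcorr_lag <- lags[best] / fs

  asym <- cbind(
    asym_logratio_delta = lr(c1$bp[, 1L], c2$bp[, 1L]),
    asym_logratio_theta = lr(c1$bp[, 2L], c2$bp[, 2L]),
    asym_logratio_alpha = lr(c1$bp[, 3L], c2$bp[, 3L]),
    asym_logratio_beta  = lr(c1$bp[, 4L], c2$bp[, 4L]),
    asym_normdiff_delta = nd(c1$bp[, 1L], c2$bp[, 1L]),
    asym_normdiff_theta = nd(c1$bp[, 2L], c2$bp[, 2L]),
    asym_normdiff_alpha = nd(c1$bp[, 3L], c2$bp[, 3L]),
    asym_normdiff_beta  = nd(c1$bp[, 4L], c2$bp[, 4L]),
    asym_logratio_total_power = lr(c1$total, c2$total),
    asym_logratio_rms = lr(c1$tf[, "rms"], c2$tf[, "rms"]),
    asym_logratio_line_length = lr(c1$tf[, "line_length"],
                                   c2$tf[, "line_length"]),
    asym_diff_zero_crossings = c1$tf[, "zero_crossings"] -
      c2$tf[, "zero_crossings"],
    asym_diff_hjorth_mobility = c1$mobility - c2$mobility,
    asym_diff_hjorth_complexity = c1$complexity - c2$complexity,
    asym_corr = corr,
    asym_xcorr_max = xcorr_max,
    asym_xcorr_lag_s = xcorr_lag,
    asym_diff_spectral_edge95 = c1$edge - c2$edge,
    asym_diff_peak_freq = c1$pk - c2$pk)

  out <- cbind(c1$feats, c2$feats, asym)
  colnames(out) <- eeg_feature_names()$name
  out[!is.finite(out)] <- 0
  out
}

#' Label windows from ground-truth seizure events
#'
#' A window is positive when at least `min_overlap` of its span overlaps a
#' ground-truth seizure interval.
#'
#' @param grid A `ws_grid`.
#' @param truth Annotation data frame with `start_s`, `end_s` (seizure rows
#'   are selected if a `label` column is present).
#' @param min_overlap Fraction of the window, default 0.5.
#' @return Logical vector, one element per window.
#' @export
label_windows <- function(grid, truth, min_overlap = 0.5) {
  if (!is.null(truth$label)) truth <- truth[truth$label == "seizure", ]
  vapply(grid$starts, function(s)
    overlap_duration(s, s + grid$win_s, truth$start_s, truth$end_s) >=
      min_overlap * grid$win_s, logical(1))
}

# shared SVM wrapper: feature standardization (fit on training data) +
# RBF-SVM with inverse-frequency class weights
train_window_classifier <- function(features, labels, cost = 1,
                                    gamma = NULL) {
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  center <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  x <- scale(features, center = center, scale = scl)
  y <- factor(ifelse(labels, "sz", "bg"), levels = c("bg", "sz"))
  n <- length(y)
  wts <- c(bg = n / (2 * sum(y == "bg")), sz = n / (2 * sum(y == "sz")))
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = wts, scale = FALSE)
  structure(list(fit = fit, center = center, scale = scl,
                 feature_names = colnames(features),
                 cost = cost, gamma = gamma),
            class = "ws_classifier")
}

#' Train the bte-EEG window classifier
#'
#' Radial-basis-function SVM on standardized features; the standardization
#' (fit on the training set) travels with the model. Class imbalance is
#' handled by inverse-frequency class weights. Default hyperparameters
#' `cost = 1`, `gamma = 1/n_features`.
#'
#' @param features Matrix `n_windows x 67` from [extract_eeg_features()].
#' @param labels Logical vector (TRUE = seizure window).
#' @param cost,gamma SVM hyperparameters.
#' @return A `ws_classifier`.
#' @export
train_eeg_classifier <- function(features, labels, cost = 1, gamma = NULL)
  train_window_classifier(features, labels, cost = cost, gamma = gamma)

#' @export
predict.ws_classifier <- function(object, newdata, threshold = 0, ...) {
  x <- scale(newdata[, object$feature_names, drop = FALSE],
             center = object$center, scale = object$scale)
  p <- stats::predict(object$fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  d <- dv[, 1L]
  # libsvm orients the decision value toward the first class in the colname
  if (startsWith(colnames(dv)[1L], "bg")) d <- -d
  list(decision = unname(d), positive = unname(d > threshold))
}

#' 8-of-10 post-processing rule
#'
#' @param group_len Number of consecutive windows per group (default 10).
#' @param min_positives Positives required within a group (default 8).
#' @return A `ws_pprule`.
#' @export
postprocess_rule <- function(group_len = 10L, min_positives = 8L) {
  stopifnot(min_positives >= 1L, min_positives <= group_len)
  structure(list(group_len = as.integer(group_len),
                 min_positives = as.integer(min_positives)),
            class = "ws_pprule")
}

#' Post-process window labels into detection events
#'
#' A group of `group_len` consecutive windows starting at window index g
#' (0-based) qualifies when it contains at least `min_positives` positive
#' windows; each qualifying group contributes the span
#' `[g * hop_s, (g + group_len) * hop_s)`. Events are the union of
#' contributed spans, merged when overlapping or contiguous, so the minimum
#' possible event duration is `group_len * hop_s` (10 s at the defaults).
#'
#' @param positives Logical/0-1 vector of window labels on the grid.
#' @param rule A [postprocess_rule()].
#' @param hop_s Window hop of the underlying grid, seconds.
#' @param scores Optional decision values per window; each event's `score`
#'   is the mean over its constituent windows.
#' @return Data frame of events: `start_s`, `end_s`, `modality = "eeg"`,
#'   `score`.
#' @export
postprocess <- function(positives, rule = postprocess_rule(), hop_s = 1,
                        scores = NULL) {
  x <- as.integer(as.logical(positives))
  k <- rule$group_len
  n <- length(x)
  if (n < k) return(empty_events("eeg"))
  cs <- c(0L, cumsum(x))
  gsum <- cs[(k + 1L):(n + 1L)] - cs[1L:(n - k + 1L)]
  g <- which(gsum >= rule$min_positives)      # 1-based group starts
  if (!length(g)) return(empty_events("eeg"))
  spans <- merge_intervals((g - 1L) * hop_s, (g - 1L + k) * hop_s)
  sc <- rep(NA_real_, nrow(spans))
  if (!is.null(scores)) {
    for (i in seq_len(nrow(spans))) {
      w <- which((seq_len(n) - 1L) * hop_s >= spans$start_s[i] - 1e-9 &
                   (seq_len(n) - 1L) * hop_s < spans$end_s[i] - 1e-9)
      sc[i] <- mean(scores[w])
    }
  }
  data.frame(start_s = spans$start_s, end_s = spans$end_s,
             modality = "eeg", score = sc, stringsAsFactors = FALSE)
}

#' Run the full bte-EEG detector on a recording
#'
#' Band-passes both EEG channels, extracts the 67 features on the 2 s / 1 s
#' grid, applies the trained classifier, and post-processes the window
#' labels into alarms of at least 10 s.
#'
#' @param recording A `ws_recording` with both EEG roles.
#' @param model A `ws_classifier` from [train_eeg_classifier()].
#' @param rule A [postprocess_rule()].
#' @param threshold Decision threshold (default 0).
#' @return Event data frame (`start_s`, `end_s`, `modality`, `score`).
#' @export
detect_eeg <- function(recording, model, rule = postprocess_rule(),
                       threshold = 0) {
  ch1 <- recording_channel(recording, "eeg_crosshead")
  ch2 <- recording_channel(recording, "eeg_ipsilateral")
  stopifnot(ch1$fs == ch2$fs)
  fs <- ch1$fs
  x1 <- eeg_bandpass(ch1$samples, fs)
  x2 <- eeg_bandpass(ch2$samples, fs)
  grid <- make_grid(min(length(x1), length(x2)), fs, win_s = 2, hop_s = 1)
  feats <- extract_eeg_features(x1, x2, fs, grid)
  pr <- predict(model, feats, threshold = threshold)
  postprocess(pr$positive, rule = rule, hop_s = grid$hop_s,
              scores = pr$decision)
}

#' Leave-one-recording-out evaluation of the bte-EEG detector
#'
#' Extracts features for every cohort recording once, then for each held-out
#' recording trains on the remainder (keeping all seizure windows and a
#' seeded subsample of background windows), detects on the held-out data,
#' and scores events against ground truth.
#'
#' @param cohort List from [gen_cohort()] (elements need `recording` and
#'   `annotations`).
#' @param rule A [postprocess_rule()].
#' @param cost,gamma SVM hyperparameters.
#' @param max_neg_per_rec Background windows kept per training recording.
#' @param seed Seed for the background subsample.
#' @return List with pooled `sensitivity`, `fd_per_24h`, and a `per_fold`
#'   data frame of counts.
#' @export
evaluate_eeg_cohort <- function(cohort, rule = postprocess_rule(),
                                cost = 1, gamma = NULL,
                                max_neg_per_rec = 250L, seed = 1L) {
  prep <- lapply(cohort, function(el) {
    ch1 <- recording_channel(el$recording, "eeg_crosshead")
    ch2 <- recording_channel(el$recording, "eeg_ipsilateral")
    fs <- ch1$fs
    x1 <- eeg_bandpass(ch1$samples, fs)
    x2 <- eeg_bandpass(ch2$samples, fs)
    grid <- make_grid(length(x1), fs, 2, 1)
    list(feats = extract_eeg_features(x1, x2, fs, grid),
         labels = label_windows(grid, el$annotations),
         grid = grid, truth = el$annotations,
         duration_s = el$recording$duration_s)
  })
  per_fold <- data.frame()
  for (i in seq_along(prep)) {
    tr <- prep[-i]
    xs <- list(); ys <- list()
    for (j in seq_along(tr)) {
      set.seed(sub_seed(seed, 300L + i * 37L + j))
      pos <- which(tr[[j]]$labels)
      neg <- which(!tr[[j]]$labels)
      if (length(neg) > max_neg_per_rec)
        neg <- sort(sample(neg, max_neg_per_rec))
      keep <- sort(c(pos, neg))
      xs[[j]] <- tr[[j]]$feats[keep, , drop = FALSE]
      ys[[j]] <- tr[[j]]$labels[keep]
    }
    model <- train_window_classifier(do.call(rbind, xs), unlist(ys),
                                     cost = cost, gamma = gamma)
    pr <- predict(model, prep[[i]]$feats)
    ev <- postprocess(pr$positive, rule = rule, hop_s = prep[[i]]$grid$hop_s,
                      scores = pr$decision)
    m <- match_events(ev, prep[[i]]$truth, prep[[i]]$duration_s)
    per_fold <- rbind(per_fold, data.frame(
      fold = i, tp = m$tp_detections, fp = m$fp_detections,
      detected = m$detected_seizures, missed = m$missed_seizures,
      duration_s = m$duration_s))
  }
  sens <- sum(per_fold$detected) /
    (sum(per_fold$detected) + sum(per_fold$missed))
  fd24 <- 86400 * sum(per_fold$fp) / sum(per_fold$duration_s)
  list(sensitivity = sens, fd_per_24h = fd24, per_fold = per_fold)
}
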