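# Seeded synthetic wearable recordings: bte-EEG background with ictal
# rhythmic bursts and artifact episodes, single-lead ECG driven by a
# configurable peri-ictal heart-rate profile, plus the packaged cohort
# metadata table. Every generator is a pure function of (config, seed).

#' Cohort metadata table (42 patients with focal epilepsy)
#'
#' Per-patient metadata of the wearable-monitoring cohort the package
#' emulates: number of seizures, seizure types (FA, FIA, F-BTC, NC),
#' seizure-onset localization and lateralization, and ictal-tachycardia
#' status (`yes` = heart-rate increase of at least 20 BPM during seizures,
#' `intermediate` = increase below 20 BPM, `no` = no increase).
#'
#' Multiset columns use the encoding `"FA:14|FIA:8"`; a bare token such as
#' `"FIA"` means all of the patient's seizures are of that kind. Use
#' [count_multiset()] to tabulate them across the cohort.
#'
#' @return Data frame with one row per patient (42 rows) and columns
#'   `patient_id`, `n_seizures`, `seizure_types`, `localization`,
#'   `lateralization`, `ictal_tachycardia`.
#' @export
table1_metadata <- function() {
  path <- system.file("extdata", "seizeit1_table1.csv", package = "wearseiz",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  df
}

#' Tabulate a multiset column of the cohort metadata
#'
#' @param metadata Data frame from [table1_metadata()].
#' @param column One of `"seizure_types"`, `"localization"`,
#'   `"lateralization"`.
#' @return Named integer vector of per-seizure counts summed over patients.
#' @export
count_multiset <- function(metadata, column) {
  out <- integer(0)
  for (i in seq_len(nrow(metadata))) {
    enc <- metadata[[column]][i]
    n <- metadata$n_seizures[i]
    parts <- strsplit(enc, "|", fixed = TRUE)[[1L]]
    for (p in parts) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
      key <- kv[1L]
      cnt <- if (length(kv) == 2L) as.integer(kv[2L]) else n
      out[key] <- (if (is.na(out[key])) 0L else out[key]) + cnt
    }
  }
  total <- sum(out)
  expect <- sum(metadata$n_seizures)
  if (total != expect)
    stop("multiset column ", column, " sums to ", total,
         " but cohort has ", expect, " seizures")
  out
}

#' Simulation configuration for one synthetic wearable recording
#'
#' Defaults describe the desk-scale study conditions: a 600 s session at
#' 250 Hz with two 40 s focal seizures, theta-range (5 Hz) ictal rhythm at
#' three times the 20 µV background, EMG-like artifact bursts at 10 per
#' hour, a 70 BPM baseline heart rate, and a responder-sized peri-ictal
#' increase of 25 BPM (the responder criterion is >= 20 BPM). A negative
#' `ictal_hr_increase` simulates mild ictal bradycardia (a non-responder).
#'
#' @param duration_s Recording length, seconds (integer number of seconds).
#' @param fs Sampling rate for EEG and ECG channels, Hz.
#' @param seizure_intervals List of `c(start_s, end_s)` half-open intervals;
#'   must be disjoint and inside `[0, duration_s)`.
#' @param ictal_eeg_freq Frequency of the ictal rhythmic discharge, Hz
#'   (theta range 3-8 Hz).
#' @param ictal_eeg_amp Peak amplitude of the ictal rhythm, µV.
#' @param background_amp Standard deviation of the background EEG, µV.
#' @param artifact_rate Artifact-burst rate, events per hour.
#' @param artifact_guard_s Guard zone around seizures that artifact bursts
#'   must avoid, seconds.
#' @param baseline_hr Baseline heart rate, BPM (40-180).
#' @param ictal_hr_increase Peri-ictal heart-rate change, BPM; >= 20 gives a
#'   responder, in (0, 20) an intermediate, <= 0 a non-responder.
#' @param hr_ramp_s Rise time of the ictal heart-rate change, seconds.
#' @param hr_wander_sd Standard deviation of the slow baseline heart-rate
#'   wander, BPM (kept <= 2).
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A list of class `ws_simconfig`.
#' @export
simulation_config <- function(duration_s = 600, fs = 250,
                              seizure_intervals = list(c(120, 160),
                                                       c(400, 440)),
                              ictal_eeg_freq = 5, ictal_eeg_amp = 60,
                              background_amp = 20,
                              artifact_rate = 10, artifact_guard_s = 30,
                              baseline_hr = 70, ictal_hr_increase = 25,
                              hr_ramp_s = 20, hr_wander_sd = 1.5,
                              seed = 1L) {
  cfg <- list(duration_s = duration_s, fs = fs,
              seizure_intervals = seizure_intervals,
              ictal_eeg_freq = ictal_eeg_freq, ictal_eeg_amp = ictal_eeg_amp,
              background_amp = background_amp, artifact_rate = artifact_rate,
              artifact_guard_s = artifact_guard_s, baseline_hr = baseline_hr,
              ictal_hr_increase = ictal_hr_increase, hr_ramp_s = hr_ramp_s,
              hr_wander_sd = hr_wander_sd, seed = as.integer(seed))
  class(cfg) <- "ws_simconfig"
  validate_simconfig(cfg)
}

validate_simconfig <- function(cfg) {
  stopifnot(cfg$duration_s > 0, cfg$fs > 0)
  if (cfg$baseline_hr < 40 || cfg$baseline_hr > 180)
    stop("baseline_hr must be in [40, 180] BPM")
  if (cfg$hr_wander_sd < 0 || cfg$hr_wander_sd > 2)
    stop("hr_wander_sd must be in [0, 2] BPM")
  iv <- cfg$seizure_intervals
  if (length(iv)) {
    m <- do.call(rbind, iv)
    if (any(m[, 1] < 0) || any(m[, 2] > cfg$duration_s) ||
        any(m[, 2] <= m[, 1]))
      stop("seizure intervals must be nonempty and inside [0, duration_s)")
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2]))
      stop("seizure intervals overlap")
    cfg$seizure_intervals <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  cfg
}

# deterministic sub-seed for generator components, kept inside 32-bit range
sub_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 127 + as.numeric(k) * 9973) %% 2147483399)

#' Generate 1/f-weighted background EEG
#'
#' Zero-mean noise whose spectrum falls off as 1/f (power), rescaled so the
#' sample standard deviation equals `amp` exactly. Identical seeds give
#' bit-identical output.
#'
#' @param duration_s Length in seconds.
#' @param fs Sampling rate, Hz.
#' @param amp Target standard deviation, µV (0 gives an all-zero trace).
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration_s * fs)` samples, µV.
#' @export
gen_background_eeg <- function(duration_s, fs, amp, seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- as.integer(round(duration_s * fs))
  if (amp == 0) return(numeric(n))
  set.seed(sub_seed(seed, 1L))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                  # two-sided frequency axis
  w <- 1 / sqrt(pmax(f, 0.5))           # flat below the 0.5 Hz passband edge
  w[1L] <- 0                            # remove DC
  x <- Re(stats::fft(X * w, inverse = TRUE)) / n
  x <- x - mean(x)
  x * amp / stats::sd(x)
}

#' Generate an ictal rhythmic EEG burst
#'
#' An amplitude-modulated sinusoid emulating the theta-range rhythmic
#' discharge seen on the cross-head bte-EEG channel during focal seizures:
#' the envelope ramps linearly from `0.3 * amp` to `amp` across the burst,
#' with background-scale 1/f noise superimposed.
#'
#' @param duration_s Burst length, seconds (0 gives an empty vector).
#' @param fs Sampling rate, Hz.
#' @param freq Discharge frequency, Hz; a warning is issued outside the
#'   0.5-35 Hz review passband (the pattern would be filtered out).
#' @param amp Peak envelope amplitude, µV.
#' @param seed Integer seed.
#' @return Numeric vector with attribute `envelope` (the noise-free ramp).
#' @export
gen_ictal_eeg <- function(duration_s, fs, freq, amp, seed = 1L) {
  stopifnot(amp > 0, fs > 0)
  if (freq < 0.5 || freq > 35)
    warning("ictal frequency ", freq,
            " Hz lies outside the 0.5-35 Hz passband and would be attenuated")
  n <- as.integer(round(duration_s * fs))
  if (n == 0L) {
    out <- numeric(0)
    attr(out, "envelope") <- numeric(0)
    return(out)
  }
  set.seed(sub_seed(seed, 2L))
  phase <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1L) / fs
  env <- amp * seq(0.3, 1, length.out = n)
  x <- env * sin(2 * pi * freq * t + phase) +
    gen_background_eeg(duration_s, fs, 0.15 * amp, seed = sub_seed(seed, 3L))
  attr(x, "envelope") <- env
  x
}

#' Generate a peri-ictal heart-rate profile
#'
#' Baseline heart rate with slow autoregressive wander (SD
#' `hr_wander_sd`, correlation time about 400 s, the time scale of
#' posture/activity drift), plus for each seizure a
#' trapezoidal excursion of `ictal_hr_increase` BPM: linear rise over
#' `hr_ramp_s` from seizure onset, a plateau until offset, then exponential
#' recovery (60 s time constant). Sampled at 1 Hz.
#'
#' @param config A [simulation_config()].
#' @return A `ws_hr_series` data frame with columns `times_s`, `bpm`.
#' @export
gen_hr_profile <- function(config) {
  stopifnot(inherits(config, "ws_simconfig"))
  t <- seq(0, config$duration_s - 1)
  n <- length(t)
  set.seed(sub_seed(config$seed, 4L))
  if (config$hr_wander_sd > 0) {
    rho <- 0.9975
    e <- stats::rnorm(n)
    w <- as.numeric(stats::filter(e, rho, method = "recursive"))
    w <- w - mean(w)
    w <- w * config$hr_wander_sd / stats::sd(w)
    # baseline wander is bounded: larger excursions would be activity bouts,
    # which are modeled separately, so rare tails are winsorized
    lim <- 2.75 * config$hr_wander_sd
    w <- pmin(lim, pmax(-lim, w))
  } else w <- numeric(n)
  bump <- numeric(n)
  for (iv in config$seizure_intervals) {
    a <- iv[1]; b <- iv[2]
    # bradycardic (negative) excursions emerge around electrographic onset,
    # so their ramp is placed just before it; tachycardic ones follow onset
    if (config$ictal_hr_increase < 0) a <- max(0, a - config$hr_ramp_s)
    r <- numeric(n)
    up <- t >= a & t < a + config$hr_ramp_s
    r[up] <- (t[up] - a) / config$hr_ramp_s
    r[t >= a + config$hr_ramp_s & t < b] <- 1
    post <- t >= b
    r[post] <- exp(-(t[post] - b) / 60)
    bump <- bump + config$ictal_hr_increase * r
  }
  hr_series(t, config$baseline_hr + w + bump)
}

hr_series <- function(times_s, bpm) {
  df <- data.frame(times_s = as.numeric(times_s), bpm = as.numeric(bpm))
  class(df) <- c("ws_hr_series", "data.frame")
  df
}

#' Synthesize a single-lead ECG from a heart-rate profile
#'
#' Beat times are obtained by stepping through the profile (the interval
#' after a beat at time t is 60/HR(t) seconds) and a fixed PQRST template of
#' Gaussian components is placed at each beat, so consecutive R-R intervals
#' equal 60/HR evaluated at each beat. The true R-peak times are returned
#' as ground truth for detector tests.
#'
#' @param hr_profile A `ws_hr_series` (1 Hz is typical); values must lie in
#'   30-220 BPM.
#' @param fs Output sampling rate, Hz.
#' @param seed Integer seed for the measurement noise.
#' @param noise_sd Additive noise SD, mV.
#' @return List with `samples` (mV), `fs`, and `rpeaks_s` (true R times).
#' @export
gen_ecg <- function(hr_profile, fs = 250, seed = 1L, noise_sd = 0.02) {
  stopifnot(inherits(hr_profile, "ws_hr_series"))
  if (any(hr_profile$bpm < 30 | hr_profile$bpm > 220))
    stop("heart-rate profile outside the supported 30-220 BPM range")
  dur <- max(hr_profile$times_s) + 1
  hr_at <- function(tt) stats::approx(hr_profile$times_s, hr_profile$bpm,
                                      xout = tt, rule = 2)$y
  beats <- numeric(ceiling(dur * 4))
  k <- 0L
  tcur <- 0.3
  while (tcur < dur - 0.5) {
    k <- k + 1L
    beats[k] <- tcur
    tcur <- tcur + 60 / hr_at(tcur)
  }
  beats <- beats[seq_len(k)]

  n <- as.integer(round(dur * fs))
  sig <- numeric(n)
  # PQRST as Gaussian components (offset s, amplitude mV, width s)
  comp <- list(c(-0.18, 0.12, 0.030),   # P
               c(-0.025, -0.15, 0.010), # Q
               c(0.00, 1.00, 0.012),    # R
               c(0.030, -0.25, 0.012),  # S
               c(0.25, 0.30, 0.050))    # T
  half <- as.integer(round(0.45 * fs))
  tpl_t <- (-half:half) / fs
  tpl <- numeric(length(tpl_t))
  for (cc in comp) tpl <- tpl + cc[2] * exp(-0.5 * ((tpl_t - cc[1]) / cc[3])^2)
  for (b in beats) {
    c0 <- as.integer(round(b * fs)) + 1L
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    sig[lo:hi] <- sig[lo:hi] + tpl[(lo - c0 + half + 1L):(hi - c0 + half + 1L)]
  }
  set.seed(sub_seed(seed, 5L))
  sig <- sig + stats::rnorm(n, sd = noise_sd)
  # the template R apex lies at the rounded beat sample
  list(samples = sig, fs = fs, rpeaks_s = (round(beats * fs)) / fs)
}

#' Generate a full synthetic wearable recording
#'
#' Builds a two-channel bte-EEG (the ictal rhythm is injected on the
#' cross-head channel and attenuated by 0.6 on the ipsilateral channel), a
#' single-lead ECG driven by the peri-ictal heart-rate profile, and a 1 Hz
#' heart-rate channel. EMG-band (20-35 Hz) high-amplitude artifact bursts
#' are placed at `artifact_rate` per hour outside a guard zone around the
#' seizures. Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with elements `recording` (a `ws_recording`), `annotations`
#'   (ground-truth seizure events), `hr_profile` (the true heart-rate
#'   series), `rpeaks_s` (true R-peak times) and `artifacts` (burst
#'   intervals).
#' @export
gen_recording <- function(config) {
  config <- validate_simconfig(config)
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))

  eeg1 <- gen_background_eeg(config$duration_s, fs, config$background_amp,
                             seed = sub_seed(config$seed, 11L))
  eeg2 <- gen_background_eeg(config$duration_s, fs, config$background_amp,
                             seed = sub_seed(config$seed, 12L))
  for (k in seq_along(config$seizure_intervals)) {
    iv <- config$seizure_intervals[[k]]
    burst <- gen_ictal_eeg(iv[2] - iv[1], fs, config$ictal_eeg_freq,
                           config$ictal_eeg_amp,
                           seed = sub_seed(config$seed, 20L + k))
    idx <- (as.integer(round(iv[1] * fs)) + 1L):(as.integer(round(iv[1] * fs)) +
                                                  length(burst))
    eeg1[idx] <- eeg1[idx] + as.numeric(burst)
    eeg2[idx] <- eeg2[idx] + 0.6 * as.numeric(burst)
  }

  # artifact bursts: band-limited 20-35 Hz noise at 4x background amplitude
  set.seed(sub_seed(config$seed, 13L))
  n_art <- stats::rpois(1, config$artifact_rate * config$duration_s / 3600)
  guard <- config$artifact_guard_s
  blocked <- lapply(config$seizure_intervals, function(iv)
    c(max(0, iv[1] - guard), min(config$duration_s, iv[2] + guard)))
  artifacts <- list()
  tries <- 0L
  while (length(artifacts) < n_art && tries < 200L * max(1L, n_art)) {
    tries <- tries + 1L
    len <- stats::runif(1, 2, 5)
    a <- stats::runif(1, 0, config$duration_s - len)
    clash <- any(vapply(c(blocked, artifacts), function(iv)
      a < iv[2] && iv[1] < a + len, logical(1)))
    if (!clash) artifacts <- c(artifacts, list(c(a, a + len)))
  }
  if (fs > 70.1) {
    bf <- signal::butter(4, c(20, 35) / (fs / 2), type = "pass")
    for (iv in artifacts) {
      m <- as.integer(round((iv[2] - iv[1]) * fs))
      raw <- stats::rnorm(m + 2L * fs)       # pad for the filter transient
      bl <- signal::filtfilt(bf, raw)[fs + seq_len(m)]
      bl <- bl / stats::sd(bl) * 4 * config$background_amp
      taper <- sin(pi * seq(0, 1, length.out = m))^2
      idx <- (as.integer(round(iv[1] * fs)) + 1L):(as.integer(round(iv[1] * fs)) + m)
      eeg1[idx] <- eeg1[idx] + bl * taper
      eeg2[idx] <- eeg2[idx] + 0.8 * bl * taper
    }
  }

  hr <- gen_hr_profile(config)
  ecg <- gen_ecg(hr, fs = fs, seed = sub_seed(config$seed, 14L))

  rec <- new_recording(
    patient_id = sprintf("sim%06d", config$seed %% 1000000L),
    channels = list(
      list(label = "EEG CrossHead", role = "eeg_crosshead",
           samples = eeg1, fs = fs),
      list(label = "EEG Ipsilateral", role = "eeg_ipsilateral",
           samples = eeg2, fs = fs),
      list(label = "ECG", role = "ecg",
           samples = ecg$samples[seq_len(n)], fs = fs),
      list(label = "HR", role = "heart_rate",
           samples = hr$bpm, fs = 1)
    ))

  ann <- if (length(config$seizure_intervals)) {
    annotation_events(
      start_s = vapply(config$seizure_intervals, `[`, numeric(1), 1L),
      end_s   = vapply(config$seizure_intervals, `[`, numeric(1), 2L),
      label = "seizure", source = "ground_truth")
  } else {
    validate_annotations(data.frame(start_s = numeric(0), end_s = numeric(0),
                                    label = character(0),
                                    source = character(0)))
  }

  list(recording = rec, annotations = ann, hr_profile = hr,
       rpeaks_s = ecg$rpeaks_s, artifacts = artifacts, config = config)
}

#' Generate a cohort of synthetic recordings
#'
#' Each recording gets its own seed (`seed + i - 1`) and seizure intervals
#' drawn at random positions (two seizures of `seizure_len_s` seconds, at
#' least 60 s apart and 60 s from either edge).
#'
#' @param n Number of recordings.
#' @param seed Base integer seed.
#' @param duration_s,fs,seizure_len_s,... Passed through to
#'   [simulation_config()]; `...` may override any other config field.
#' @return List of [gen_recording()] results.
#' @export
gen_cohort <- function(n = 10, seed = 0L, duration_s = 600, fs = 250,
                       seizure_len_s = 40, ...) {
  lapply(seq_len(n), function(i) {
    si <- as.integer(seed) + i - 1L
    set.seed(sub_seed(si, 99L))
    repeat {
      a1 <- stats::runif(1, 60, duration_s / 2 - seizure_len_s - 60)
      a2 <- stats::runif(1, duration_s / 2 + 60,
                         duration_s - seizure_len_s - 60)
      if (a2 - (a1 + seizure_len_s) >= 60) break
    }
    cfg <- simulation_config(
      duration_s = duration_s, fs = fs,
      seizure_intervals = list(c(a1, a1 + seizure_len_s),
                               c(a2, a2 + seizure_len_s)),
      seed = si, ...)
    gen_recording(cfg)
  })
}
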