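# Event-based scoring of alarms against ground truth, the four headline
# metrics (sensitivity, FD/24h, PPV, F1), reader scoring for the
# semi-automated review, stratified breakdowns, and rater statistics.

#' Match alarm events against ground-truth seizures
#'
#' Overlap is any nonempty intersection of half-open intervals. A true
#' positive is an alarm overlapping at least one seizure (several alarms on
#' one seizure all count as TPs, so `tp_detections` can exceed
#' `detected_seizures`); a false positive is an alarm overlapping none; a
#' seizure is detected when at least one alarm overlaps it, otherwise
#' missed (FN).
#'
#' @param alarms Event data frame (`start_s`, `end_s`).
#' @param ground_truth Annotation data frame; rows with `label == "seizure"`
#'   are used when a `label` column is present.
#' @param duration_s Total recording duration, seconds (> 0).
#' @return A `ws_match`: list with `tp_detections`, `fp_detections`,
#'   `detected_seizures`, `missed_seizures`, `duration_s`.
#' @export
match_events <- function(alarms, ground_truth, duration_s) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.null(ground_truth$label))
    ground_truth <- ground_truth[ground_truth$label == "seizure", ]
  a_hit <- overlaps_any(alarms$start_s, alarms$end_s,
                        ground_truth$start_s, ground_truth$end_s)
  s_hit <- overlaps_any(ground_truth$start_s, ground_truth$end_s,
                        alarms$start_s, alarms$end_s)
  structure(list(tp_detections = sum(a_hit),
                 fp_detections = sum(!a_hit),
                 detected_seizures = sum(s_hit),
                 missed_seizures = sum(!s_hit),
                 duration_s = duration_s),
            class = "ws_match")
}

#' Compute the event-based performance metrics
#'
#' Sensitivity = detected/(detected + missed) seizures; FD/24h =
#' 86400 * FP / duration; PPV = TP/(TP + FP) over detections; F1 is the
#' harmonic mean of sensitivity and PPV. Sensitivity deliberately uses
#' seizure counts while PPV uses detection counts, since one seizure can
#' attract several detections. Ratios of the form 0/0 are returned as `NA`
#' and listed in the `undefined` field, never silently coerced to 0.
#'
#' @param match A `ws_match` from [match_events()].
#' @return A `ws_score`: list with `sensitivity`, `fd_per_24h`, `ppv`,
#'   `f1`, the raw counts, and `undefined` (character vector of flagged
#'   metrics).
#' @export
compute_metrics <- function(match) {
  undef <- character(0)
  n_sz <- match$detected_seizures + match$missed_seizures
  sens <- if (n_sz > 0) match$detected_seizures / n_sz else {
    undef <- c(undef, "sensitivity"); NA_real_ }
  n_det <- match$tp_detections + match$fp_detections
  ppv <- if (n_det > 0) match$tp_detections / n_det else {
    undef <- c(undef, "ppv"); NA_real_ }
  fd24 <- 86400 * match$fp_detections / match$duration_s
  f1 <- if (is.na(sens) || is.na(ppv)) {
    undef <- c(undef, "f1"); NA_real_
  } else if (sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
  structure(list(sensitivity = sens, fd_per_24h = fd24, ppv = ppv, f1 = f1,
                 tp_detections = match$tp_detections,
                 fp_detections = match$fp_detections,
                 detected_seizures = match$detected_seizures,
                 missed_seizures = match$missed_seizures,
                 duration_s = match$duration_s,
                 undefined = undef),
            class = "ws_score")
}

#' @export
print.ws_score <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.1f%%  FD/24h %.1f  PPV %.1f%%  F1 %.2f  (TP %d FP %d FN %d)\n",
    100 * x$sensitivity, x$fd_per_24h, 100 * x$ppv, x$f1,
    x$tp_detections, x$fp_detections, x$missed_seizures))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' F1 score from sensitivity and positive predictive value
#'
#' Harmonic mean `2 * sens * ppv / (sens + ppv)`; 0 when either input is 0,
#' `NA` when either is `NA`.
#'
#' @param sensitivity,ppv Fractions in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(sensitivity, ppv) {
  if (is.na(sensitivity) || is.na(ppv)) return(NA_real_)
  if (sensitivity + ppv == 0) return(0)
  2 * sensitivity * ppv / (sensitivity + ppv)
}

#' Score a reader's relabelling of the alarms
#'
#' In the semi-automated review the reader only sees the algorithm's
#' alarms. A TP is an alarm the reader labelled `seizure` that overlaps a
#' ground-truth seizure; an FP is labelled `seizure` without overlap; an FN
#' is an alarm that overlaps a seizure but was not labelled `seizure`.
#' Seizures the algorithm never alarmed on are excluded from every count
#' (the algorithm's own misses are not charged to the reader).
#'
#' @param reader_labels Data frame with `alarm_id` and `label`
#'   (`seizure` / `artifact` / `other`).
#' @param alarms Event data frame with an `alarm_id` column.
#' @param ground_truth Annotation data frame of true seizures.
#' @param duration_s Recording duration for the FD/24h rate.
#' @return A `ws_score` (sensitivity here is TP/(TP+FN) over alarms).
#' @export
score_reader <- function(reader_labels, alarms, ground_truth, duration_s) {
  if (!all(reader_labels$alarm_id %in% alarms$alarm_id))
    stop("reader label references unknown alarm_id: ",
         setdiff(reader_labels$alarm_id, alarms$alarm_id)[1L])
  bad <- setdiff(reader_labels$label, c("seizure", "artifact", "other"))
  if (length(bad)) stop("unknown reader label: ", bad[1L])
  if (!is.null(ground_truth$label))
    ground_truth <- ground_truth[ground_truth$label == "seizure", ]
  hit <- overlaps_any(alarms$start_s, alarms$end_s,
                      ground_truth$start_s, ground_truth$end_s)
  said_sz <- alarms$alarm_id %in%
    reader_labels$alarm_id[reader_labels$label == "seizure"]
  tp <- sum(hit & said_sz)
  fp <- sum(!hit & said_sz)
  fn <- sum(hit & !said_sz)
  undef <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    undef <- c(undef, "sensitivity"); NA_real_ }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else {
    undef <- c(undef, "ppv"); NA_real_ }
  f1 <- if (is.na(sens) || is.na(ppv)) { undef <- c(undef, "f1"); NA_real_
  } else if (sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
  structure(list(sensitivity = sens,
                 fd_per_24h = 86400 * fp / duration_s,
                 ppv = ppv, f1 = f1,
                 tp_detections = tp, fp_detections = fp,
                 detected_seizures = tp, missed_seizures = fn,
                 duration_s = duration_s, undefined = undef),
            class = "ws_score")
}

#' Stratified event-based scores
#'
#' Pools per-recording match inputs within each level of a stratifying
#' variable (seizure-onset localization, ictal-tachycardia status, ...) and
#' computes the metrics per stratum. Per-stratum counts sum to the global
#' counts because the recordings partition the cohort.
#'
#' @param per_recording List; each element a list with `alarms`, `truth`,
#'   `duration_s`, and a `strata` named list/character of stratum keys.
#' @param by Name of the stratum key to use.
#' @return Named list of `ws_score`, one per stratum level.
#' @export
stratify_scores <- function(per_recording, by) {
  keys <- vapply(per_recording, function(el) as.character(el$strata[[by]]),
                 character(1))
  out <- list()
  for (lev in unique(keys)) {
    sel <- per_recording[keys == lev]
    counts <- lapply(sel, function(el)
      match_events(el$alarms, el$truth, el$duration_s))
    pooled <- structure(list(
      tp_detections = sum(vapply(counts, `[[`, numeric(1), "tp_detections")),
      fp_detections = sum(vapply(counts, `[[`, numeric(1), "fp_detections")),
      detected_seizures = sum(vapply(counts, `[[`, numeric(1),
                                     "detected_seizures")),
      missed_seizures = sum(vapply(counts, `[[`, numeric(1),
                                   "missed_seizures")),
      duration_s = sum(vapply(counts, `[[`, numeric(1), "duration_s"))),
      class = "ws_match")
    out[[lev]] <- compute_metrics(pooled)
  }
  out
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement from the product of the marginals. When `p_e = 1` exactly
#' (both raters constant on the same category) kappa is defined as 1 if the
#' observed agreement is also perfect, otherwise `NA` with a warning.
#'
#' @param labels_a,labels_b Paired categorical sequences of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label sequences differ in length")
  if (!length(labels_a)) stop("empty label sequences")
  levs <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = levs)
  b <- factor(labels_b, levels = levs)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    if (abs(1 - p_o) < 1e-12) return(1)
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' McNemar's test from discordant-pair counts
#'
#' `b` and `c` are the counts of pairs on which exactly one of the two
#' classifiers/readers is correct. Small discordant totals
#' (`b + c < exact_threshold`) use the exact two-sided binomial test
#' (p = min(1, 2 P[X <= min(b, c)] with X ~ Bin(b + c, 1/2))); larger ones
#' the continuity-corrected chi-squared test with 1 df.
#'
#' @param b,c Non-negative discordant counts.
#' @param exact_threshold Switch-over total (default 25).
#' @return List with `statistic` (chi-squared, `NA` for the exact branch),
#'   `p_value`, `method`, and `degenerate` (TRUE when `b = c = 0`).
#' @export
mcnemar_counts <- function(b, c, exact_threshold = 25) {
  if (b < 0 || c < 0) stop("discordant counts must be non-negative")
  if (b + c == 0)
    return(list(statistic = NA_real_, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  if (b + c < exact_threshold) {
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
    return(list(statistic = NA_real_, p_value = p, method = "exact",
                degenerate = FALSE))
  }
  m <- matrix(c(0, b, c, 0), nrow = 2)   # x[2,1] = b, x[1,2] = c
  ht <- stats::mcnemar.test(m, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "chi-squared", degenerate = FALSE)
}

#' Discordant-pair counts from paired correctness sequences
#'
#' @param correct_a,correct_b Logical vectors: whether each paired decision
#'   was correct under condition a and condition b.
#' @return List with `b` (a right, b wrong) and `c` (a wrong, b right).
#' @export
discordant_counts <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  list(b = sum(correct_a & !correct_b), c = sum(!correct_a & correct_b))
}
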