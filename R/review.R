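# Semi-automated review workflow: package the fused alarms for human
# relabelling, ingest the reader's labels, and summarize review effort.

#' Prepare a review package from alarms and ground truth
#'
#' Assigns stable ids to the alarms and builds the merged annotation table
#' given to readers: every alarm appears with provenance `algorithm`; for
#' correct detections the ground-truth interval is substituted by the alarm
#' interval (the original extent is retained in `orig_start_s` /
#' `orig_end_s`); seizures with no alarm remain as ground-truth rows.
#' Display defaults follow the review setup: 10 s EEG window, 10 min
#' heart-rate window, 70 µV/cm amplitude scale.
#'
#' @param alarms Event data frame (`start_s`, `end_s`, `modality`).
#' @param ground_truth Annotation data frame of true seizures.
#' @param duration_s Recording duration; alarms outside it are an error.
#' @return List with `items` (review items: `alarm_id`, interval, modality,
#'   display context) and `annotations` (the merged table).
#' @export
prepare_review <- function(alarms, ground_truth, duration_s) {
  alarms <- as.data.frame(alarms)
  if (nrow(alarms) &&
      (any(alarms$start_s < 0) || any(alarms$end_s > duration_s + 1e-9)))
    stop("alarm outside the recording")
  if (!is.null(ground_truth$label))
    ground_truth <- ground_truth[ground_truth$label == "seizure", ]
  alarms <- alarms[order(alarms$start_s, alarms$end_s), , drop = FALSE]
  n <- nrow(alarms)
  ids <- sprintf("alarm_%04d", seq_len(n))
  items <- data.frame(
    alarm_id = ids,
    start_s = alarms$start_s, end_s = alarms$end_s,
    modality = if (is.null(alarms$modality)) rep("fused", n) else
      alarms$modality,
    eeg_window_s = rep(10, n), hr_window_s = rep(600, n),
    eeg_scale_uV_per_cm = rep(70, n),
    stringsAsFactors = FALSE)

  orig_s <- rep(NA_real_, n); orig_e <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hit <- which(intervals_overlap(alarms$start_s[i], alarms$end_s[i],
                                   ground_truth$start_s, ground_truth$end_s))
    if (length(hit)) {
      orig_s[i] <- ground_truth$start_s[hit[1L]]
      orig_e[i] <- ground_truth$end_s[hit[1L]]
    }
  }
  covered <- overlaps_any(ground_truth$start_s, ground_truth$end_s,
                          alarms$start_s, alarms$end_s)
  merged <- rbind(
    data.frame(alarm_id = ids, start_s = alarms$start_s,
               end_s = alarms$end_s, label = rep("alarm", n),
               source = rep("algorithm", n),
               orig_start_s = orig_s, orig_end_s = orig_e,
               stringsAsFactors = FALSE),
    if (any(!covered)) data.frame(
      alarm_id = NA_character_,
      start_s = ground_truth$start_s[!covered],
      end_s = ground_truth$end_s[!covered],
      label = "seizure", source = "ground_truth",
      orig_start_s = NA_real_, orig_end_s = NA_real_,
      stringsAsFactors = FALSE))
  merged <- merged[order(merged$start_s, merged$end_s), , drop = FALSE]
  rownames(merged) <- NULL
  list(items = items, annotations = merged)
}

#' Ingest a reader's relabelling file
#'
#' @param path CSV with header `alarm_id,label,reader_id,review_time_s`
#'   (the time column may be empty).
#' @param review_items Items from [prepare_review()].
#' @return Data frame of reader labels; duplicate (alarm, reader) rows keep
#'   the last occurrence with a warning.
#' @export
ingest_reader_labels <- function(path, review_items) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("alarm_id", "label", "reader_id")
  if (!all(need %in% names(df)))
    stop("reader file needs columns ", paste(need, collapse = ", "))
  if (is.null(df$review_time_s)) df$review_time_s <- NA_real_
  bad <- which(!df$alarm_id %in% review_items$alarm_id)
  if (length(bad))
    stop("unknown alarm_id '", df$alarm_id[bad[1L]], "' at row ", bad[1L])
  bad <- which(!df$label %in% c("seizure", "artifact", "other"))
  if (length(bad))
    stop("unknown label '", df$label[bad[1L]], "' at row ", bad[1L])
  key <- paste(df$alarm_id, df$reader_id)
  if (anyDuplicated(key)) {
    warning("duplicate reader labels; keeping the last of each")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Summarize a review session
#'
#' Label histograms per reader plus the review-time summary normalized to
#' minutes per 24 h of recording (the session's total review time scaled by
#' `86400 / duration_s`). Timing fields are omitted when no times were
#' recorded.
#'
#' @param labels Reader labels from [ingest_reader_labels()].
#' @param duration_s Duration of the reviewed recording, seconds.
#' @return List with `label_counts` (table reader x label), `n_labels`,
#'   and, when available, `review_min_per_24h` (per reader) and
#'   `mean_review_min_per_24h`.
#' @export
summarize_review <- function(labels, duration_s) {
  out <- list(label_counts = table(labels$reader_id, labels$label),
              n_labels = nrow(labels))
  if (any(is.finite(labels$review_time_s))) {
    per_reader <- tapply(labels$review_time_s, labels$reader_id,
                         function(v) sum(v, na.rm = TRUE))
    norm <- as.numeric(per_reader) / 60 * 86400 / duration_s
    names(norm) <- names(per_reader)
    out$review_min_per_24h <- norm
    out$mean_review_min_per_24h <- mean(norm)
  }
  out
}
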