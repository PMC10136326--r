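# Late decision fusion of the two unimodal alarm streams.

#' Fuse EEG and ECG alarms with the 'OR' strategy
#'
#' The multimodal alarm stream is the union of the unimodal detections:
#' every bte-EEG event is kept unchanged, and an ECG event is kept only when
#' it overlaps no EEG event — on overlap the bte-EEG detection segment is
#' taken and the ECG event is dropped entirely (also when one ECG event
#' spans several EEG events). Touching events (`[a,b)` then `[b,c)`) do not
#' overlap under the half-open convention, so both survive.
#'
#' @param eeg_events,ecg_events Event data frames (`start_s`, `end_s`,
#'   optionally `modality`, `score`), each internally non-overlapping.
#' @return Data frame sorted by `start_s` with per-event provenance in
#'   `modality`; no two retained events overlap.
#' @export
fuse_or <- function(eeg_events, ecg_events) {
  eeg_events <- normalize_events(eeg_events, "eeg")
  ecg_events <- normalize_events(ecg_events, "ecg")
  assert_sorted_nonoverlapping(eeg_events, "eeg events")
  assert_sorted_nonoverlapping(ecg_events, "ecg events")
  keep <- !overlaps_any(ecg_events$start_s, ecg_events$end_s,
                        eeg_events$start_s, eeg_events$end_s)
  out <- rbind(eeg_events, ecg_events[keep, , drop = FALSE])
  out <- out[order(out$start_s, out$end_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_events <- function(ev, modality) {
  ev <- as.data.frame(ev)
  if (nrow(ev) == 0L) return(empty_events(modality))
  if (is.null(ev$modality)) ev$modality <- modality
  if (is.null(ev$score)) ev$score <- NA_real_
  ev[, c("start_s", "end_s", "modality", "score")]
}
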