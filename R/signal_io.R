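# Recording container + EDF and annotation-CSV I/O.
#
# Time convention (shared by every module): float seconds from recording
# start, half-open intervals [start_s, end_s). All downstream code consumes
# in-memory objects; no module re-reads files.

ANNOT_LABELS  <- c("seizure", "artifact", "other", "alarm")
ANNOT_SOURCES <- c("ground_truth", "algorithm", "reader")
CHANNEL_ROLES <- c("eeg_crosshead", "eeg_ipsilateral", "ecg", "heart_rate")

#' Construct a multichannel wearable recording
#'
#' A `ws_recording` bundles the channels of one wearable session: two
#' behind-the-ear EEG channels (one cross-head, one ipsilateral to the
#' seizure-onset hemisphere), a single-lead ECG, and optionally a derived
#' heart-rate trace. Each channel carries its own sampling rate; EEG samples
#' are in microvolts, ECG in millivolts, heart rate in BPM.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param channels List of channels, each a list with elements `label`
#'   (character), `role` (one of `"eeg_crosshead"`, `"eeg_ipsilateral"`,
#'   `"ecg"`, `"heart_rate"`), `samples` (numeric vector) and `fs`
#'   (sampling rate in Hz).
#' @return An object of class `ws_recording` with fields `patient_id`,
#'   `channels` and `duration_s`.
#' @export
new_recording <- function(patient_id, channels) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (length(channels) == 0L) stop("a recording needs at least one channel")
  durs <- vapply(channels, function(ch) {
    if (!all(c("label", "role", "samples", "fs") %in% names(ch)))
      stop("each channel needs label, role, samples, fs")
    if (!ch$role %in% CHANNEL_ROLES)
      stop("unknown channel role: ", ch$role)
    if (!is.numeric(ch$fs) || ch$fs <= 0) stop("channel fs must be > 0")
    length(ch$samples) / ch$fs
  }, numeric(1))
  dur <- max(durs)
  # channels must agree on duration to within one sample of the slowest rate
  slack <- 1 / min(vapply(channels, function(ch) ch$fs, numeric(1)))
  if (any(abs(durs - dur) > slack + 1e-9))
    stop("channel durations disagree by more than one sample")
  structure(
    list(patient_id = patient_id, channels = channels, duration_s = dur),
    class = "ws_recording"
  )
}

#' @export
print.ws_recording <- function(x, ...) {
  cat(sprintf("<ws_recording> patient %s, %.1f s, %d channel(s)\n",
              x$patient_id, x$duration_s, length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %-16s %-16s %6g Hz  %d samples\n",
                ch$label, ch$role, ch$fs, length(ch$samples)))
  invisible(x)
}

#' Extract a channel from a recording by role
#'
#' @param recording A `ws_recording`.
#' @param role Channel role to extract.
#' @return The channel (list with `label`, `role`, `samples`, `fs`), or an
#'   error if the role is absent or ambiguous.
#' @export
recording_channel <- function(recording, role) {
  hits <- Filter(function(ch) ch$role == role, recording$channels)
  if (length(hits) == 0L) stop("recording has no channel with role ", role)
  if (length(hits) > 1L) stop("recording has multiple channels with role ", role)
  hits[[1L]]
}

#' Default EDF label-to-role mapping
#'
#' EDF channel labels vary between vendors, so roles are assigned by a
#' configurable table of case-insensitive regular expressions tried in order.
#'
#' @return Named character vector: regex pattern -> role.
#' @export
default_label_roles <- function() {
  c("cross"                 = "eeg_crosshead",
    "ipsi"                  = "eeg_ipsilateral",
    "\\becg\\b|\\bekg\\b|ecg" = "ecg",
    "heart|\\bhr\\b"        = "heart_rate")
}

map_label_role <- function(label, label_roles) {
  for (i in seq_along(label_roles)) {
    if (grepl(names(label_roles)[i], label, ignore.case = TRUE))
      return(unname(label_roles[i]))
  }
  NA_character_
}

# ---- EDF (European Data Format) ------------------------------------------
# Minimal 16-bit EDF layer: fixed 1 s data records, physical scaling per
# channel. Sampling rates must therefore be integers and the recording an
# integer number of seconds — true for all wearable recordings this package
# generates or consumes.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, blank-padded
}

edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Physical min/max per channel are chosen symmetric about zero, covering the
#' signal range without clipping; samples are stored as 16-bit integers over
#' a symmetric digital range, so the worst-case round-trip error is half of
#' one quantization step (physical range / 65534) and an exact zero is
#' stored losslessly.
#'
#' @param recording A `ws_recording`; all sampling rates must be whole Hz and
#'   the duration a whole number of seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ws_recording"))
  for (ch in recording$channels) {
    if (!all(is.finite(ch$samples)))
      stop("channel ", ch$label, " contains non-finite samples")
    if (abs(ch$fs - round(ch$fs)) > 1e-9)
      stop("EDF writer requires integer sampling rates (got ", ch$fs, ")")
  }
  n_rec <- round(recording$duration_s)
  if (abs(recording$duration_s - n_rec) > 1e-6)
    stop("EDF writer requires an integer number of seconds")
  ns <- length(recording$channels)

  phys <- lapply(recording$channels, function(ch) {
    pm <- max(abs(ch$samples))
    if (pm == 0) pm <- 1
    # round the bound up to 3 significant digits so the header string is exact
    f <- 10^(floor(log10(pm)) - 2)
    pm <- ceiling(pm / f) * f
    c(-pm, pm)
  })

  unit_for <- function(role) switch(role,
    eeg_crosshead = "uV", eeg_ipsilateral = "uV",
    ecg = "mV", heart_rate = "bpm")

  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s) writeChar(s, con, eos = NULL)
  w(edf_pad("0", 8))
  w(edf_pad(recording$patient_id, 80))
  w(edf_pad("wearseiz recording", 80))
  w("01.01.00"); w("00.00.00")
  w(edf_pad(256 * (ns + 1), 8))
  w(edf_pad("", 44))
  w(edf_pad(n_rec, 8))
  w(edf_pad("1", 8))
  w(edf_pad(ns, 4))
  for (ch in recording$channels) w(edf_pad(ch$label, 16))
  for (ch in recording$channels) w(edf_pad("", 80))
  for (ch in recording$channels) w(edf_pad(unit_for(ch$role), 8))
  for (p in phys) w(edf_num(p[1]))
  for (p in phys) w(edf_num(p[2]))
  # symmetric digital range so a physical zero maps exactly to digital zero
  for (ch in recording$channels) w(edf_pad("-32767", 8))
  for (ch in recording$channels) w(edf_pad("32767", 8))
  for (ch in recording$channels) w(edf_pad("", 80))
  for (ch in recording$channels) w(edf_pad(round(ch$fs), 8))
  for (ch in recording$channels) w(edf_pad("", 32))

  spr <- vapply(recording$channels, function(ch) as.integer(round(ch$fs)),
                integer(1))
  dig <- lapply(seq_len(ns), function(i) {
    ch <- recording$channels[[i]]; p <- phys[[i]]
    x <- ch$samples
    if (length(x) < spr[i] * n_rec)  # pad a short trailing second with zeros
      x <- c(x, numeric(spr[i] * n_rec - length(x)))
    d <- round((x - p[1]) / (p[2] - p[1]) * 65534 - 32767)
    as.integer(pmin(32767, pmax(-32767, d)))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path Path to an EDF/EDF+ file with one data-record layout this
#'   package writes (16-bit samples).
#' @param label_roles Named character vector mapping label regexes to channel
#'   roles; see [default_label_roles()]. Channels matching no pattern are
#'   dropped with a warning; if no EEG or ECG channel can be mapped at all,
#'   a channel-mapping error names the unmapped labels.
#' @return A `ws_recording` with signals in physical units.
#' @export
read_recording <- function(path, label_roles = default_label_roles()) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L || nchar(s, type = "bytes") < n)
      stop("corrupt or truncated EDF header in ", path)
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  patient_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(ns) || ns < 1L)
    stop("corrupt EDF header in ", path)
  labels  <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)            # transducer
  units   <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_   <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_   <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_   <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_   <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr     <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  raw <- lapply(seq_len(ns), function(i) integer(0))
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, what = "integer", n = per_rec, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < per_rec) stop("truncated EDF data in ", path)
    off <- 0L
    for (i in seq_len(ns)) {
      raw[[i]] <- c(raw[[i]], block[(off + 1L):(off + spr[i])])
      off <- off + spr[i]
    }
  }

  roles <- vapply(labels, map_label_role, character(1),
                  label_roles = label_roles)
  if (!any(roles %in% c("eeg_crosshead", "eeg_ipsilateral", "ecg"),
           na.rm = TRUE)) {
    stop("no recognizable EEG/ECG channel labels; unmapped: ",
         paste(labels[is.na(roles)], collapse = ", "))
  }
  if (any(is.na(roles)))
    warning("dropping unmapped channels: ",
            paste(labels[is.na(roles)], collapse = ", "))

  keep <- which(!is.na(roles))
  channels <- lapply(keep, function(i) {
    gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    list(label = labels[i], role = roles[i],
         samples = (raw[[i]] - dmin_[i]) * gain + pmin_[i],
         fs = spr[i] / rec_dur)
  })
  new_recording(patient_id = patient_id, channels = channels)
}

# ---- annotation events ----------------------------------------------------

#' Construct a table of annotation events
#'
#' Events are half-open intervals `[start_s, end_s)` in seconds from the
#' start of the recording, each with a label (`seizure`, `artifact`, `other`
#' or `alarm`) and a provenance (`ground_truth`, `algorithm` or `reader`).
#'
#' @param start_s,end_s Numeric vectors of interval bounds (seconds).
#' @param label Character vector of labels (recycled).
#' @param source Character vector of provenances (recycled).
#' @return A data.frame of class `ws_annotations`, sorted by `start_s`.
#' @export
annotation_events <- function(start_s, end_s, label = "seizure",
                              source = "ground_truth") {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label), source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df, duration_s = NULL) {
  required <- c("start_s", "end_s", "label", "source")
  if (!all(required %in% names(df)))
    stop("annotations need columns ", paste(required, collapse = ", "))
  bad <- which(!(df$end_s > df$start_s))
  if (length(bad))
    stop("end_s <= start_s at row ", bad[1L])
  bad <- which(df$start_s < 0)
  if (length(bad)) stop("negative start_s at row ", bad[1L])
  bad <- which(!df$label %in% ANNOT_LABELS)
  if (length(bad))
    stop("unknown label '", df$label[bad[1L]], "' at row ", bad[1L])
  bad <- which(!df$source %in% ANNOT_SOURCES)
  if (length(bad))
    stop("unknown source '", df$source[bad[1L]], "' at row ", bad[1L])
  if (!is.null(duration_s)) {
    bad <- which(df$end_s > duration_s + 1e-9)
    if (length(bad)) stop("event beyond recording end at row ", bad[1L])
  }
  df <- df[order(df$start_s, df$end_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ws_annotations", "data.frame")
  df
}

#' Read annotation events from a CSV sidecar
#'
#' @param path CSV file with header `start_s,end_s,label,source`.
#' @param duration_s Optional recording duration used to validate bounds.
#' @return A `ws_annotations` data.frame sorted by `start_s` (empty when the
#'   file has only a header).
#' @export
read_annotations <- function(path, duration_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(start_s = "numeric", end_s = "numeric",
                                       label = "character",
                                       source = "character"))
  validate_annotations(df, duration_s = duration_s)
}

#' Write annotation events to a CSV sidecar
#'
#' Round trip through [read_annotations()] is lossless.
#'
#' @param events A `ws_annotations` data.frame (or anything coercible:
#'   columns `start_s,end_s,label,source`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  events <- validate_annotations(as.data.frame(events))
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
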