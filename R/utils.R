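# Internal interval helpers. All intervals are half-open [start, end).

# merge overlapping or contiguous intervals; m is a 2-column matrix
merge_intervals <- function(start_s, end_s) {
  if (length(start_s) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  o <- order(start_s, end_s)
  s <- start_s[o]; e <- end_s[o]
  ms <- s[1L]; me <- e[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= me + 1e-9) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  data.frame(start_s = c(out_s, ms), end_s = c(out_e, me))
}

# logical: does [a1,b1) overlap [a2,b2)? (vectorized over the first pair)
intervals_overlap <- function(a1, b1, a2, b2) a1 < b2 & a2 < b1

# for each [a,b) in x: does it overlap any interval in y?
overlaps_any <- function(xs, xe, ys, ye) {
  if (length(xs) == 0L) return(logical(0))
  if (length(ys) == 0L) return(rep(FALSE, length(xs)))
  vapply(seq_along(xs), function(i)
    any(xs[i] < ye & ys < xe[i]), logical(1))
}

# total overlap duration of [a,b) with a set of intervals
overlap_duration <- function(a, b, ys, ye) {
  if (length(ys) == 0L) return(0)
  sum(pmax(0, pmin(b, ye) - pmax(a, ys)))
}

assert_sorted_nonoverlapping <- function(events, what = "events") {
  if (nrow(events) == 0L) return(invisible(events))
  o <- order(events$start_s)
  ev <- events[o, , drop = FALSE]
  if (any(ev$start_s[-1L] < ev$end_s[-nrow(ev)] - 1e-9))
    stop(what, " contain overlapping intervals")
  invisible(ev)
}

empty_events <- function(modality = character(0)) {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             modality = modality[0], score = numeric(0),
             stringsAsFactors = FALSE)
}
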