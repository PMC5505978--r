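#' Beat occurrence sequence
#'
#' A `beat_sequence` holds the occurrence times (seconds) of successive
#' R peaks, strictly increasing, together with an optional rhythm label
#' ("NSR", "AF" or "unlabeled") and a free-text record identifier.
#'
#' @param times numeric vector of beat occurrence instants, seconds;
#'   strictly increasing, finite, at least 2 values.
#' @param label rhythm class tag.
#' @param record_id free-text provenance tag.
#' @return an object of class `beat_sequence`.
#' @examples
#' beat_sequence(c(0, 0.8, 1.6, 2.4), label = "NSR")
#' @export
beat_sequence <- function(times, label = "unlabeled", record_id = "") {
  times <- as.numeric(times)
  if (length(times) < 2L)
    rr_abort("rrgamma_insufficient_data",
             "a beat sequence needs at least 2 beats")
  if (any(!is.finite(times)))
    rr_abort("rrgamma_invalid_beat_order", "beat times must all be finite")
  if (any(diff(times) <= 0))
    rr_abort("rrgamma_invalid_beat_order",
             "beat times must be strictly increasing")
  structure(list(times = times, label = as.character(label)[1],
                 record_id = as.character(record_id)[1]),
            class = "beat_sequence")
}

#' @export
print.beat_sequence <- function(x, ...) {
  cat(sprintf("<beat_sequence> %d beats over %.3f s, label = %s%s\n",
              length(x$times), diff(range(x$times)), x$label,
              if (nzchar(x$record_id)) paste0(" [", x$record_id, "]") else ""))
  invisible(x)
}

#' @export
length.beat_sequence <- function(x) length(x$times)

#' Build the RR tachogram from beat times
#'
#' Interval `n` is `times[n+1] - times[n]`; its timestamp is the
#' occurrence time of the beat that terminates it (causal convention,
#' computable in real time).
#'
#' @param beats a [beat_sequence()].
#' @return an [rr_series()] of order 0 with one fewer element than beats.
#' @examples
#' beats_to_rr(beat_sequence(c(0, 0.6, 1.5)))
#' @export
beats_to_rr <- function(beats) {
  stopifnot(inherits(beats, "beat_sequence"))
  rr_series(values = diff(beats$times), timestamps = beats$times[-1],
            order = 0L, label = beats$label, record_id = beats$record_id)
}

#' Truncate a beat sequence to a short observation window
#'
#' Retains beats whose elapsed time from the first beat is at most
#' `duration_s` (boundary inclusive). The window is anchored at the first
#' beat of the record.
#'
#' @param beats a [beat_sequence()].
#' @param duration_s window length, seconds (> 0).
#' @return a [beat_sequence()] spanning at most `duration_s` seconds.
#' @export
truncate_to_duration <- function(beats, duration_s) {
  stopifnot(inherits(beats, "beat_sequence"), duration_s > 0)
  keep <- (beats$times - beats$times[1]) <= duration_s + 1e-12
  if (sum(keep) < 2L)
    rr_abort("rrgamma_insufficient_data",
             sprintf("window of %.3g s retains fewer than 2 beats", duration_s))
  beat_sequence(beats$times[keep], label = beats$label,
                record_id = beats$record_id)
}
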