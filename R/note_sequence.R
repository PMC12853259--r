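#' Construct a monophonic note sequence
#'
#' A `note_sequence` is the package's core melody container: an ordered table
#' of notes (onset, duration, MIDI pitch) together with a time signature and a
#' text label. Onsets are absolute seconds; a note occupies the half-open
#' interval `[onset, onset + duration)`. Monophony is enforced: onsets must be
#' strictly increasing and no two onsets may fall within 1 ms of each other.
#'
#' @param onset_s numeric vector of note onsets in seconds, strictly increasing.
#' @param duration_s numeric vector of note durations in seconds, all positive.
#' @param pitch integer vector of MIDI note numbers in `[0, 127]`.
#' @param time_signature integer vector `c(numerator, denominator)`; numerator
#'   must be one of 2, 3, 4, 6 and denominator one of 4, 8.
#' @param label optional text identifier carried through pairing and fusion.
#'
#' @return An object of class `note_sequence`: a list with elements `notes`
#'   (data.frame with columns `onset_s`, `duration_s`, `pitch`),
#'   `time_signature` and `label`.
#' @examples
#' note_sequence(c(0, 0.5, 1), c(0.4, 0.4, 0.4), c(60, 62, 64), c(4, 4))
#' @export
note_sequence <- function(onset_s, duration_s, pitch, time_signature = c(4L, 4L),
                          label = "") {
  n <- length(onset_s)
  if (n == 0L) stop("empty melody")
  if (length(duration_s) != n || length(pitch) != n)
    stop("onset_s, duration_s and pitch must have equal length")
  if (any(diff(onset_s) < 1e-3))
    stop("onsets must be strictly increasing with >= 1 ms separation (monophonic)")
  if (any(duration_s <= 0)) stop("all durations must be > 0")
  if (any(pitch < 0 | pitch > 127)) stop("pitches must lie in [0, 127]")
  validate_time_signature(time_signature)
  structure(
    list(
      notes = data.frame(onset_s = as.numeric(onset_s),
                         duration_s = as.numeric(duration_s),
                         pitch = as.integer(round(pitch))),
      time_signature = as.integer(time_signature),
      label = as.character(label)
    ),
    class = "note_sequence"
  )
}

validate_time_signature <- function(ts) {
  if (length(ts) != 2L) stop("time_signature must be c(numerator, denominator)")
  if (!ts[1] %in% c(2L, 3L, 4L, 6L)) stop("time signature numerator must be 2, 3, 4 or 6")
  if (!ts[2] %in% c(4L, 8L)) stop("time signature denominator must be 4 or 8")
  invisible(ts)
}

#' @export
length.note_sequence <- function(x) nrow(x$notes)

#' @export
print.note_sequence <- function(x, ...) {
  cat(sprintf("<note_sequence> %s: %d notes, %d/%d, %.2f s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$notes), x$time_signature[1], x$time_signature[2],
              sequence_duration(x)))
  invisible(x)
}

#' Total duration of a note sequence
#'
#' Offset of the final note relative to time zero.
#'
#' @param seq a [note_sequence()].
#' @return duration in seconds.
#' @export
sequence_duration <- function(seq) {
  with(seq$notes, onset_s[nrow(seq$notes)] + duration_s[nrow(seq$notes)])
}

#' Extract pitch and inter-onset-interval viewpoints
#'
#' Decomposes a melody into the two symbolic dimensions on which expectation
#' is modelled: the chromatic pitch sequence (viewpoint `cpitch`) and the
#' inter-onset-interval sequence (viewpoint `ioi`). The IOI sequence is
#' aligned to notes 2..n: the first note has no IOI.
#'
#' @param seq a [note_sequence()] with at least two notes.
#' @return list with `pitch_seq` (length n) and `ioi_seq` (length n - 1,
#'   seconds, all positive).
#' @examples
#' m <- note_sequence(c(0, 0.5, 1.25), rep(0.2, 3), c(60, 62, 64))
#' viewpoints(m)$ioi_seq  # 0.5 0.75
#' @export
viewpoints <- function(seq) {
  stopifnot(inherits(seq, "note_sequence"))
  if (nrow(seq$notes) < 2L) stop("viewpoints need at least 2 notes")
  list(pitch_seq = seq$notes$pitch,
       ioi_seq = diff(seq$notes$onset_s))
}

#' Duration of one measure in seconds
#'
#' Computed from the time signature and the beat period: a measure holds
#' `numerator` beats of `4 / denominator` quarter-note units each.
#'
#' @param seq a [note_sequence()].
#' @param quarter_s duration of a quarter note in seconds.
#' @return measure duration in seconds.
#' @export
measure_duration <- function(seq, quarter_s) {
  ts <- seq$time_signature
  ts[1] * (4 / ts[2]) * quarter_s
}

#' Annotate metrical downbeats
#'
#' Marks the notes that fall on a measure boundary — the downbeat, the first
#' beat of a measure and typically the strongest metrical accent. The measure
#' grid is anchored at absolute time 0 by default (melodies conventionally
#' start at the grid origin); `anacrusis_s` shifts the grid to accommodate
#' pickup measures.
#'
#' @param seq a [note_sequence()].
#' @param quarter_s quarter-note duration in seconds (sets the measure grid).
#' @param tolerance_s a note counts as on-grid when its onset is within this
#'   tolerance of a measure boundary. Default 1 ms: symbolic input is exact;
#'   raise it for humanized MIDI.
#' @param anacrusis_s grid offset in seconds for pickup measures (default 0).
#' @return list of class `downbeat_mask` with `is_downbeat` (logical per
#'   note) and `measure_duration_s`.
#' @examples
#' m <- note_sequence(seq(0, 2, by = 0.5), rep(0.4, 5), rep(60, 5), c(3, 4))
#' annotate_downbeats(m, quarter_s = 0.5)$is_downbeat  # T F F T F
#' @export
annotate_downbeats <- function(seq, quarter_s, tolerance_s = 1e-3,
                               anacrusis_s = 0) {
  stopifnot(inherits(seq, "note_sequence"))
  beat_s <- (4 / seq$time_signature[2]) * quarter_s
  if (tolerance_s >= beat_s / 2) stop("tolerance too coarse")
  meas_s <- measure_duration(seq, quarter_s)
  t0 <- anacrusis_s
  rel <- seq$notes$onset_s - t0
  # distance to the nearest measure boundary (grid may extend before t0)
  dist <- abs(rel - round(rel / meas_s) * meas_s)
  structure(list(is_downbeat = dist <= tolerance_s,
                 measure_duration_s = meas_s),
            class = "downbeat_mask")
}

#' Export a note table
#'
#' Flattens a melody (and optional downbeat mask) to a data.frame suitable
#' for TSV export, with 0-based note indices.
#'
#' @param seq a [note_sequence()].
#' @param mask optional [annotate_downbeats()] result.
#' @return data.frame with columns `index`, `onset_s`, `duration_s`, `pitch`,
#'   `is_downbeat`.
#' @export
note_table <- function(seq, mask = NULL) {
  n <- nrow(seq$notes)
  data.frame(index = seq_len(n) - 1L,
             seq$notes,
             is_downbeat = if (is.null(mask)) rep(NA, n) else mask$is_downbeat)
}
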