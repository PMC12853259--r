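#' Beat-structure group of a melody
#'
#' Classifies a melody's time signature into the two beat-structure families
#' used for chimeric pairing: triple beats (3/4, 3/8, 6/8) versus
#' duple/quadruple beats (2/4, 4/4, 4/8).
#'
#' @param seq a [note_sequence()].
#' @return `"TRIPLE"` or `"DUPLE_QUAD"`.
#' @export
beat_group <- function(seq) {
  stopifnot(inherits(seq, "note_sequence"))
  key <- paste(seq$time_signature, collapse = "/")
  if (key %in% c("3/4", "3/8", "6/8")) return("TRIPLE")
  if (key %in% c("2/4", "4/4", "4/8")) return("DUPLE_QUAD")
  stop("time signature ", key, " outside beat-group taxonomy")
}

#' Pair pieces across beat groups by note count
#'
#' Greedy cross-group matching: pieces from the triple and duple/quadruple
#' groups are sorted by note count and swept with two pointers, emitting the
#' admissible pair with the smallest note-count difference at each step.
#' Every returned pair has one member from each group, note counts differing
#' by at most `max_note_count_diff`, and no piece used twice.
#'
#' @param pieces list of [note_sequence()] objects.
#' @param max_note_count_diff largest admissible `|n1 - n2|` (default 5).
#' @return list of length-2 lists `(triple piece, duple/quadruple piece)`;
#'   empty (with a warning) when no admissible pair exists.
#' @export
pair_collection <- function(pieces, max_note_count_diff = 5L) {
  grp <- vapply(pieces, beat_group, "")
  tri <- pieces[grp == "TRIPLE"]
  dup <- pieces[grp == "DUPLE_QUAD"]
  if (length(tri) == 0L || length(dup) == 0L) {
    warning("no admissible cross-group pair")
    return(list())
  }
  tri <- tri[order(vapply(tri, length, 0L))]
  dup <- dup[order(vapply(dup, length, 0L))]
  nt <- vapply(tri, length, 0L)
  nd <- vapply(dup, length, 0L)
  pairs <- list()
  i <- 1L; j <- 1L
  while (i <= length(tri) && j <= length(dup)) {
    d <- nt[i] - nd[j]
    if (abs(d) <= max_note_count_diff) {
      pairs[[length(pairs) + 1L]] <- list(tri[[i]], dup[[j]])
      i <- i + 1L; j <- j + 1L
    } else if (d > 0) j <- j + 1L else i <- i + 1L
  }
  if (length(pairs) == 0L) warning("no admissible cross-group pair")
  pairs
}

#' Fuse the pitch of one melody with the timing of another
#'
#' Builds a chimeric melody: note i takes its pitch from `pitch_source` and
#' its onset and duration from `time_source`, for i = 1..m where m is the
#' shorter length. Matching always starts at the beginning of both pieces so
#' the context prior is preserved in each dimension. The time signature is
#' inherited from the time source, whose metrical grid the chimera follows.
#'
#' @param pitch_source,time_source [note_sequence()] objects of length >= 2.
#' @return a [note_sequence()] of length `min(n_pitch, n_time)`.
#' @export
fuse_chimeric <- function(pitch_source, time_source) {
  stopifnot(inherits(pitch_source, "note_sequence"),
            inherits(time_source, "note_sequence"))
  if (length(pitch_source) < 2L || length(time_source) < 2L)
    stop("fusion needs sequences of length >= 2")
  m <- min(length(pitch_source), length(time_source))
  note_sequence(
    onset_s = time_source$notes$onset_s[seq_len(m)],
    duration_s = time_source$notes$duration_s[seq_len(m)],
    pitch = pitch_source$notes$pitch[seq_len(m)],
    time_signature = time_source$time_signature,
    label = paste0("chimera[p:", pitch_source$label, "|t:", time_source$label, "]")
  )
}

#' Build a full stimulus set from a cross-group pair
#'
#' From two originals in different beat groups, constructs the two chimeric
#' counterparts: `chimeric_a` carries the pitch of `p1` on the timing of
#' `p2`, and `chimeric_b` the pitch of `p2` on the timing of `p1`.
#'
#' @param p1,p2 [note_sequence()] objects from different beat groups.
#' @return list of class `stimulus_set` with elements `original_1`,
#'   `original_2`, `chimeric_a`, `chimeric_b` and `provenance`.
#' @export
build_stimulus_set <- function(p1, p2) {
  if (beat_group(p1) == beat_group(p2))
    stop("stimulus set requires a cross-group pair")
  structure(
    list(original_1 = p1, original_2 = p2,
         chimeric_a = fuse_chimeric(p1, p2),
         chimeric_b = fuse_chimeric(p2, p1),
         provenance = c(source_1 = p1$label, source_2 = p2$label)),
    class = "stimulus_set"
  )
}

#' Filter pieces by minimum duration
#'
#' Stimulus-length screen: keeps pieces whose total duration exceeds a
#' threshold (default 25 s).
#'
#' @param pieces list of [note_sequence()] objects.
#' @param min_duration_s minimum duration in seconds.
#' @return the surviving subset of `pieces`.
#' @export
filter_min_duration <- function(pieces, min_duration_s = 25) {
  pieces[vapply(pieces, sequence_duration, 0) > min_duration_s]
}
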