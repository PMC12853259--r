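# Minimal Standard MIDI File (SMF) I/O for monophonic melodies.
# Scope: type 0/1 files, note on/off, tempo and time-signature meta events.
# Timing: ticks-per-quarter division only (no SMPTE).

TICKS_PER_QUARTER <- 960L

vlq_encode <- function(x) {
  stopifnot(x >= 0)
  bytes <- as.raw(bitwAnd(x, 0x7F))
  x <- bitwShiftR(x, 7L)
  while (x > 0) {
    bytes <- c(as.raw(bitwOr(bitwAnd(x, 0x7F), 0x80)), bytes)
    x <- bitwShiftR(x, 7L)
  }
  bytes
}

vlq_decode <- function(raw, pos) {
  val <- 0L
  repeat {
    b <- as.integer(raw[pos]); pos <- pos + 1L
    val <- bitwOr(bitwShiftL(val, 7L), bitwAnd(b, 0x7F))
    if (b < 0x80) break
  }
  list(value = val, pos = pos)
}

u16 <- function(x) as.raw(c(bitwShiftR(x, 8L) %% 256L, x %% 256L))
u32 <- function(x) as.raw(c(bitwShiftR(x, 24L) %% 256L, bitwShiftR(x, 16L) %% 256L,
                            bitwShiftR(x, 8L) %% 256L, x %% 256L))
read_u16 <- function(raw, pos) as.integer(raw[pos]) * 256L + as.integer(raw[pos + 1L])
read_u32 <- function(raw, pos) {
  sum(as.numeric(raw[pos:(pos + 3L)]) * c(2^24, 2^16, 2^8, 1))
}

#' Write a melody as a Standard MIDI File
#'
#' Serialises a [note_sequence()] as an SMF type-0 file with one track
#' carrying a tempo meta event, a time-signature meta event and the
#' note-on/note-off pairs. [read_midi()] inverts it within the tick
#' resolution (about 0.5 ms at the default tempo).
#'
#' @param seq a [note_sequence()].
#' @param path output file path.
#' @param quarter_s quarter-note duration in seconds written as the fixed
#'   tempo (default 0.5 s, i.e. 120 BPM).
#' @return `path`, invisibly.
#' @export
write_midi <- function(seq, path, quarter_s = 0.5) {
  stopifnot(inherits(seq, "note_sequence"))
  if (nrow(seq$notes) == 0L) stop("empty melody")
  div <- TICKS_PER_QUARTER
  to_ticks <- function(t) as.integer(round(t / quarter_s * div))

  # event list: (tick, rank, raw bytes); rank orders offs before ons at a tick
  on_ticks <- to_ticks(seq$notes$onset_s)
  off_ticks <- to_ticks(seq$notes$onset_s + seq$notes$duration_s)
  ev_ticks <- c(on_ticks, off_ticks)
  ev_rank <- c(rep(1L, length(on_ticks)), rep(0L, length(off_ticks)))
  ev_bytes <- c(
    lapply(seq$notes$pitch, function(p) as.raw(c(0x90, p, 64))),
    lapply(seq$notes$pitch, function(p) as.raw(c(0x80, p, 0)))
  )
  ord <- order(ev_ticks, ev_rank)

  track <- c(
    vlq_encode(0L), as.raw(c(0xFF, 0x51, 0x03)),
    as.raw(c(bitwShiftR(round(quarter_s * 1e6), 16L) %% 256L,
             bitwShiftR(round(quarter_s * 1e6), 8L) %% 256L,
             round(quarter_s * 1e6) %% 256L)),
    vlq_encode(0L), as.raw(c(0xFF, 0x58, 0x04)),
    as.raw(c(seq$time_signature[1], as.integer(log2(seq$time_signature[2])), 24L, 8L))
  )
  prev <- 0L
  for (i in ord) {
    track <- c(track, vlq_encode(ev_ticks[i] - prev), ev_bytes[[i]])
    prev <- ev_ticks[i]
  }
  track <- c(track, vlq_encode(0L), as.raw(c(0xFF, 0x2F, 0x00)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), u32(6L), u16(0L), u16(1L), u16(div),
             charToRaw("MTrk"), u32(length(track)), track), con)
  invisible(path)
}

parse_track <- function(raw, pos, end) {
  events <- list()
  tick <- 0
  status <- NULL
  while (pos < end) {
    d <- vlq_decode(raw, pos); pos <- d$pos
    tick <- tick + d$value
    b <- as.integer(raw[pos])
    if (b >= 0x80) { status <- b; pos <- pos + 1L }
    if (is.null(status)) stop("malformed MIDI: running status without prior event")
    hi <- bitwAnd(status, 0xF0)
    if (status == 0xFF) {                       # meta
      type <- as.integer(raw[pos]); pos <- pos + 1L
      d <- vlq_decode(raw, pos); pos <- d$pos
      data <- if (d$value > 0) raw[pos:(pos + d$value - 1L)] else raw[0]
      pos <- pos + d$value
      events[[length(events) + 1L]] <- list(tick = tick, kind = "meta",
                                            type = type, data = data)
      status <- NULL
      if (type == 0x2F) break
    } else if (status %in% c(0xF0, 0xF7)) {     # sysex: skip
      d <- vlq_decode(raw, pos); pos <- d$pos + d$value
      status <- NULL
    } else if (hi %in% c(0x80L, 0x90L, 0xA0L, 0xB0L, 0xE0L)) {
      p1 <- as.integer(raw[pos]); p2 <- as.integer(raw[pos + 1L]); pos <- pos + 2L
      if (hi == 0x90L && p2 > 0) {
        events[[length(events) + 1L]] <- list(tick = tick, kind = "on", pitch = p1)
      } else if (hi == 0x80L || (hi == 0x90L && p2 == 0)) {
        events[[length(events) + 1L]] <- list(tick = tick, kind = "off", pitch = p1)
      }
    } else if (hi %in% c(0xC0L, 0xD0L)) {
      pos <- pos + 1L
    } else stop("malformed MIDI: unknown status byte ", status)
  }
  list(events = events, pos = pos)
}

#' Read a monophonic melody from a Standard MIDI File
#'
#' Parses an SMF type 0 or 1 file containing a single monophonic melody and
#' returns a [note_sequence()] with onsets in seconds. Two notes starting
#' within 1 ms of each other are rejected as polyphonic; a note still
#' sounding when the next starts is truncated at the next onset (monophonic
#' enforcement).
#'
#' @param path input file path.
#' @param quarter_s if supplied, a fixed quarter-note duration in seconds
#'   that overrides any embedded tempo events; otherwise the embedded tempo
#'   map is used (default 120 BPM when the file carries no tempo event).
#' @param time_signature fallback `c(numerator, denominator)` when the file
#'   carries no time-signature meta event; without either, an error.
#' @param label label for the returned sequence (default: file base name).
#' @return a [note_sequence()].
#' @export
read_midi <- function(path, quarter_s = NULL, time_signature = NULL,
                      label = sub("\\.midi?$", "", basename(path))) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:4]) != "MThd") stop("not a Standard MIDI File")
  fmt <- read_u16(raw, 9L)
  ntrk <- read_u16(raw, 11L)
  div <- read_u16(raw, 13L)
  if (fmt > 1L) stop("unsupported SMF format ", fmt)
  if (div >= 0x8000) stop("SMPTE time division not supported")

  pos <- 15L
  events <- list()
  for (k in seq_len(ntrk)) {
    if (rawToChar(raw[pos:(pos + 3L)]) != "MTrk") stop("malformed MIDI: missing MTrk")
    len <- read_u32(raw, pos + 4L)
    tr <- parse_track(raw, pos + 8L, pos + 8L + len)
    events <- c(events, tr$events)
    pos <- pos + 8L + len
  }
  events <- events[order(vapply(events, `[[`, 0, "tick"))]

  # tempo map: (tick, us per quarter); fixed policy overrides embedded tempo
  tempo_ticks <- 0; tempo_us <- 500000
  ts <- time_signature
  tempi <- list()
  for (e in events) {
    if (e$kind == "meta" && e$type == 0x51)
      tempi[[length(tempi) + 1L]] <- c(e$tick, sum(as.numeric(e$data) * c(2^16, 2^8, 1)))
    if (e$kind == "meta" && e$type == 0x58 && is.null(ts))
      ts <- c(as.integer(e$data[1]), 2L^as.integer(e$data[2]))
  }
  if (is.null(ts)) stop("missing time signature: none embedded and none supplied")
  if (!is.null(quarter_s)) tempi <- list(c(0, quarter_s * 1e6))
  if (length(tempi) == 0L) tempi <- list(c(0, 500000))
  tmap <- do.call(rbind, tempi)
  tick_to_s <- function(tick) {
    # piecewise-linear through the tempo changes
    vapply(tick, function(tk) {
      secs <- 0; prev_tick <- 0; prev_us <- tmap[1, 2]
      for (r in seq_len(nrow(tmap))) {
        if (tmap[r, 1] >= tk) break
        secs <- secs + (tmap[r, 1] - prev_tick) * prev_us * 1e-6 / div
        prev_tick <- tmap[r, 1]; prev_us <- tmap[r, 2]
      }
      secs + (tk - prev_tick) * prev_us * 1e-6 / div
    }, 0)
  }

  ons <- Filter(function(e) e$kind == "on", events)
  offs <- Filter(function(e) e$kind == "off", events)
  if (length(ons) == 0L) stop("empty melody")
  on_t <- tick_to_s(vapply(ons, `[[`, 0, "tick"))
  on_p <- vapply(ons, `[[`, 0, "pitch")
  if (any(diff(on_t) < 1e-3)) stop("polyphonic input: simultaneous note onsets")

  # match each note-on with the first later note-off of the same pitch
  off_t <- tick_to_s(vapply(offs, `[[`, 0, "tick"))
  off_p <- vapply(offs, `[[`, 0, "pitch")
  used <- rep(FALSE, length(offs))
  dur <- vapply(seq_along(ons), function(i) {
    j <- which(!used & off_p == on_p[i] & off_t > on_t[i] + 1e-9)[1]
    if (is.na(j)) stop("malformed MIDI: unterminated note")
    used[j] <<- TRUE
    off_t[j] - on_t[i]
  }, 0)
  # truncate overlaps at the next onset
  if (length(on_t) > 1L) {
    nxt <- c(on_t[-1], Inf)
    dur <- pmin(dur, nxt - on_t)
  }
  note_sequence(on_t, dur, on_p, ts, label = label)
}
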