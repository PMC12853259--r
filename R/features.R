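# Regressor construction on the EEG sample grid.
# Onsets are binned with round-half-up: at the default 125 samples/s the bins
# are 8 ms wide, so the tie rule is documented and deterministic.

round_half_up <- function(x) floor(x + 0.5)

grid_length <- function(fs, duration_s) as.integer(round_half_up(fs * duration_s))

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Note-onset impulse train
#'
#' Places a unit impulse at the sample nearest each (masked) note onset.
#' Two notes mapping to the same sample is an error: raise `fs` or reject
#' the stimulus.
#'
#' @param seq a [note_sequence()].
#' @param mask optional logical per note (default all `TRUE`).
#' @param fs sample rate of the regressor grid (default 125 samples/s).
#' @param duration_s signal duration; must cover the last onset.
#' @return numeric vector of length `round(fs * duration_s)`.
#' @export
impulse_train <- function(seq, mask = NULL, fs = 125, duration_s = sequence_duration(seq)) {
  scaled_impulse_train(seq, values = as.numeric(if (is.null(mask))
    rep(1, length(seq)) else mask), fs = fs, duration_s = duration_s)
}

#' Impulse train with per-note amplitudes
#'
#' Like [impulse_train()] but each impulse takes the note's feature value
#' (e.g. surprisal); notes with value zero contribute no impulse. Used to
#' turn note-level expectation features into continuous-time regressors.
#'
#' @param seq a [note_sequence()].
#' @param values numeric per-note amplitudes, same length as the melody
#'   (IOI-aligned features put 0 at note 1).
#' @param fs,duration_s as in [impulse_train()].
#' @return numeric vector of length `round(fs * duration_s)`.
#' @export
scaled_impulse_train <- function(seq, values, fs = 125,
                                 duration_s = sequence_duration(seq)) {
  stopifnot(inherits(seq, "note_sequence"), fs > 0)
  n_note <- length(seq)
  if (length(values) != n_note) stop("values length must match note count")
  n <- grid_length(fs, duration_s)
  idx <- round_half_up(seq$notes$onset_s * fs) + 1L
  if (any(idx > n)) stop("duration_s does not cover the last onset")
  if (anyDuplicated(idx)) stop("two notes map to one sample; raise fs or reject stimulus")
  x <- numeric(n)
  x[idx] <- values
  x
}

#' Onset and downbeat regressors for an original piece
#'
#' The downbeat regressor `DBo` marks the onsets of downbeat notes with unit
#' impulses; its nonzero samples are by construction a subset of the onset
#' regressor's.
#'
#' @param seq a [note_sequence()].
#' @param mask a [annotate_downbeats()] result (or logical vector per note).
#' @param fs,duration_s regressor grid, as in [impulse_train()].
#' @return named list with `onset` and `DBo` signals.
#' @export
downbeat_regressors_original <- function(seq, mask, fs = 125,
                                         duration_s = sequence_duration(seq)) {
  m <- if (inherits(mask, "downbeat_mask")) mask$is_downbeat else mask
  if (length(m) != length(seq)) stop("mask length must match note count")
  list(onset = impulse_train(seq, fs = fs, duration_s = duration_s),
       DBo = impulse_train(seq, mask = m, fs = fs, duration_s = duration_s))
}

#' Onset and decoupled downbeat regressors for a chimeric piece
#'
#' In a chimera the downbeat splits into two: `DBct` marks notes that were
#' downbeats in the time source (and hence are downbeats of the chimera,
#' since downbeats are temporally defined), `DBcp` marks notes that were
#' downbeats in the pitch source, and the interaction `DBcpt` marks notes
#' that are both. Masks are aligned by note index because fusion always
#' matches notes from the beginning.
#'
#' @param chim the chimeric [note_sequence()] (length m).
#' @param pitch_src_mask,time_src_mask downbeat masks of the pitch and time
#'   sources ([annotate_downbeats()] results or logical vectors), length
#'   >= m; truncated to m.
#' @param fs,duration_s regressor grid.
#' @return named list with `onset`, `DBct`, `DBcp`, `DBcpt` signals.
#' @export
downbeat_regressors_chimeric <- function(chim, pitch_src_mask, time_src_mask,
                                         fs = 125,
                                         duration_s = sequence_duration(chim)) {
  mp <- if (inherits(pitch_src_mask, "downbeat_mask")) pitch_src_mask$is_downbeat else pitch_src_mask
  mt <- if (inherits(time_src_mask, "downbeat_mask")) time_src_mask$is_downbeat else time_src_mask
  m <- length(chim)
  if (length(mp) < m || length(mt) < m) stop("mask shorter than chimeric length")
  mp <- mp[seq_len(m)]; mt <- mt[seq_len(m)]
  list(onset = impulse_train(chim, fs = fs, duration_s = duration_s),
       DBct = impulse_train(chim, mask = mt, fs = fs, duration_s = duration_s),
       DBcp = impulse_train(chim, mask = mp, fs = fs, duration_s = duration_s),
       DBcpt = impulse_train(chim, mask = mp & mt, fs = fs, duration_s = duration_s))
}

#' Expectation-feature regressors
#'
#' Turns the per-note surprisal/entropy table of [sequence_expectations()]
#' into four impulse-amplitude regressors on the EEG grid. IOI features are
#' aligned from note 2; note 1 carries amplitude 0. Feature values are
#' z-scored across notes per trial by default.
#'
#' @param seq the [note_sequence()] the features belong to.
#' @param feats data.frame from [sequence_expectations()].
#' @param fs,duration_s regressor grid.
#' @param z z-score feature amplitudes per trial (default `TRUE`).
#' @return named list with `Sp`, `Ep`, `St`, `Et` signals.
#' @export
expectation_regressors <- function(seq, feats, fs = 125,
                                   duration_s = sequence_duration(seq),
                                   z = TRUE) {
  one <- function(v) {
    v[is.na(v)] <- 0
    if (z) {
      nz <- v != 0
      v[nz] <- zscore(v[nz])
    }
    scaled_impulse_train(seq, v, fs = fs, duration_s = duration_s)
  }
  list(Sp = one(feats$Sp), Ep = one(feats$Ep),
       St = one(feats$St), Et = one(feats$Et))
}

#' Render a melody as damped harmonic tones
#'
#' Simple additive synthesis used to obtain an acoustic waveform for
#' spectral-flux computation: each note is a sum of four harmonics with 1/h
#' amplitudes and an exponential decay, at the MIDI-standard tuning
#' (pitch 69 = 440 Hz), equal velocity across notes. The mixed waveform is
#' normalized to a root mean square of 0.01.
#'
#' @param seq a [note_sequence()].
#' @param fs_audio audio sample rate (default 48000 Hz).
#' @param decay_s exponential amplitude decay time constant (default 0.3 s).
#' @return numeric waveform of length `round(fs_audio * total duration)`.
#' @export
render_tones <- function(seq, fs_audio = 48000, decay_s = 0.3) {
  stopifnot(inherits(seq, "note_sequence"))
  n <- grid_length(fs_audio, sequence_duration(seq))
  wav <- numeric(n)
  f0 <- 440 * 2^((seq$notes$pitch - 69) / 12)
  for (i in seq_len(length(seq))) {
    i0 <- round_half_up(seq$notes$onset_s[i] * fs_audio) + 1L
    len <- min(grid_length(fs_audio, seq$notes$duration_s[i]), n - i0 + 1L)
    t <- (seq_len(len) - 1L) / fs_audio
    env <- exp(-t / decay_s)
    tone <- numeric(len)
    for (h in 1:4) tone <- tone + sin(2 * pi * h * f0[i] * t) / h
    wav[i0:(i0 + len - 1L)] <- wav[i0:(i0 + len - 1L)] + env * tone
  }
  rms <- sqrt(mean(wav^2))
  if (rms > 0) wav <- wav * (0.01 / rms)
  wav
}

#' Spectral flux of an audio waveform on the regressor grid
#'
#' Frame-to-frame half-wave-rectified positive difference of the magnitude
#' spectrogram (1024-sample Hann windows, 50% overlap), summed over
#' frequency, resampled to the regressor rate and z-scored per trial.
#' Silent audio yields an all-zero signal with a warning.
#'
#' @param audio mono waveform.
#' @param fs_audio audio sample rate (default 48000 Hz).
#' @param fs_out regressor grid rate (default 125 samples/s).
#' @param n_fft,hop STFT window and hop sizes (defaults 1024 / 512 samples).
#' @return numeric vector of length `round(fs_out * duration)`.
#' @export
spectral_flux <- function(audio, fs_audio = 48000, fs_out = 125,
                          n_fft = 1024L, hop = n_fft %/% 2L) {
  n_out <- grid_length(fs_out, length(audio) / fs_audio)
  if (all(audio == 0)) {
    warning("silent audio: spectral flux is all zero")
    return(numeric(n_out))
  }
  win <- signal::hanning(n_fft)
  starts <- seq(1L, length(audio) - n_fft + 1L, by = hop)
  frames <- vapply(starts, function(s) audio[s:(s + n_fft - 1L)] * win,
                   numeric(n_fft))
  mag <- Mod(stats::mvfft(frames))[1:(n_fft / 2 + 1), , drop = FALSE]
  flux <- c(0, colSums(pmax(mag[, -1, drop = FALSE] -
                            mag[, -ncol(mag), drop = FALSE], 0)))
  # polyphase resampling from the frame rate to the regressor rate
  frame_rate <- fs_audio / hop
  frac <- rational_approx(fs_out / frame_rate)
  res <- signal::resample(flux, frac[1], frac[2])
  # frame k is centred at (start + n_fft/2) samples; align and fit the grid
  offset <- round_half_up((n_fft / 2) / fs_audio * fs_out)
  out <- numeric(n_out)
  keep <- seq_len(min(length(res), n_out - offset))
  out[offset + keep] <- res[keep]
  zscore(out)
}

rational_approx <- function(x, max_den = 512L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round_half_up(x * q)
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(as.integer(p), q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Assemble a named regressor set
#'
#' Bundles time-aligned signals on a common grid, validating that all have
#' the same length and that every downbeat train is a subset of the onset
#' train.
#'
#' @param signals named list of equal-length numeric vectors.
#' @param fs grid rate.
#' @return object of class `regressor_set` (list with `fs`, `duration_s`,
#'   `signals`).
#' @export
regressor_set <- function(signals, fs = 125) {
  stopifnot(is.list(signals), !is.null(names(signals)))
  len <- unique(vapply(signals, length, 0L))
  if (length(len) != 1L) stop("all signals must have the same length")
  if ("onset" %in% names(signals)) {
    on_nz <- signals$onset != 0
    for (nm in intersect(names(signals), c("DBo", "DBct", "DBcp", "DBcpt"))) {
      if (any(signals[[nm]] != 0 & !on_nz))
        stop(nm, " impulses are not a subset of the onset train")
    }
  }
  structure(list(fs = fs, duration_s = len / fs, signals = signals),
            class = "regressor_set")
}
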