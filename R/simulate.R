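# Seeded synthetic study generator: metrical melodies, ground-truth response
# kernels, and simulated multichannel EEG with the statistical structure the
# encoding analysis assumes, so every stage is verifiable by parameter
# recovery without external data.

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code
}

#' Generate a metrical monophonic melody
#'
#' Emulates a folk-style monophonic melody: onsets fall on a metrical grid
#' (IOIs drawn from 0.5, 1, 1.5 or 2 beats), and pitches follow a seeded
#' first-order Markov chain over a diatonic set that favours small steps.
#' Deterministic for a given seed.
#'
#' @param time_signature `c(numerator, denominator)` from the beat-group
#'   taxonomy.
#' @param n_notes number of notes (>= 4).
#' @param quarter_s quarter-note duration in seconds (default 0.45 s, so 60
#'   notes span roughly half a minute).
#' @param seed RNG seed.
#' @param pitch_markov_order order of the pitch chain; only 1 is supported.
#' @param label sequence label.
#' @return a [note_sequence()].
#' @export
generate_melody <- function(time_signature, n_notes, quarter_s = 0.45,
                            seed = 1L, pitch_markov_order = 1L,
                            label = sprintf("sim%d", seed)) {
  validate_time_signature(time_signature)
  if (n_notes < 4L) stop("n_notes must be >= 4")
  if (pitch_markov_order != 1L) stop("only first-order pitch chains are supported")
  with_seed(seed, {
    beat_s <- (4 / time_signature[2]) * quarter_s
    ioi_beats <- sample(c(0.5, 1, 1.5, 2), n_notes - 1L, replace = TRUE,
                        prob = c(0.3, 0.45, 0.15, 0.1))
    onsets <- c(0, cumsum(ioi_beats)) * beat_s
    scale_set <- c(60L, 62L, 64L, 65L, 67L, 69L, 71L, 72L)  # C major octave
    pitches <- integer(n_notes)
    pitches[1] <- sample(scale_set, 1L)
    for (i in 2:n_notes) {
      step <- abs(seq_along(scale_set) - match(pitches[i - 1L], scale_set))
      pitches[i] <- sample(scale_set, 1L, prob = exp(-step / 1.2))
    }
    durs <- c(diff(onsets), beat_s) * 0.9
    note_sequence(onsets, durs, pitches, time_signature, label = label)
  })
}

gauss_bump <- function(lags_ms, center_ms, width_ms, amp) {
  amp * exp(-0.5 * ((lags_ms - center_ms) / width_ms)^2)
}

#' Ground-truth response kernel bank
#'
#' Builds smooth per-regressor kernels over the lag grid with the canonical
#' auditory morphology: the onset kernel has positive P1 (~80 ms) and P2
#' (~185 ms) deflections; the downbeat kernel a ~185 ms peak and a negative
#' ~650 ms dip; expectation kernels are smooth mid-latency shapes; the
#' pitch-by-time interaction kernel is zero unless enabled. A frontocentral
#' channel weight map (max 1) projects the single-source kernels to the
#' montage.
#'
#' @param fs sample rate (default 125).
#' @param lags integer lags in samples; window must cover 0-700 ms.
#' @param channels channel names (default: the packaged 32-channel montage).
#' @param interaction amplitude of the DBcpt kernel's 185 ms peak
#'   (default 0: no interaction).
#' @param dbcp_amp amplitude of the DBcp kernel (default 0).
#' @return object of class `kernel_bank`: list with `kernels` (named list
#'   of length-L vectors), `channel_weights` (named, max 1), `lags`,
#'   `lags_ms`, `fs`.
#' @export
default_kernels <- function(fs = 125, lags = lag_samples(fs = fs),
                            channels = montage_adjacency()$channels,
                            interaction = 0, dbcp_amp = 0) {
  lags_ms <- lags / fs * 1000
  if (min(lags_ms) > 0 || max(lags_ms) < 700)
    stop("lag window must cover 0-700 ms")
  k <- list(
    flux  = gauss_bump(lags_ms, 100, 30, 0.6),
    onset = gauss_bump(lags_ms, 80, 18, 0.8) + gauss_bump(lags_ms, 185, 35, 1.2),
    Sp = gauss_bump(lags_ms, 200, 50, 0.7) + gauss_bump(lags_ms, 420, 80, -0.35),
    Ep = gauss_bump(lags_ms, 230, 55, 0.5) + gauss_bump(lags_ms, 450, 90, -0.25),
    St = gauss_bump(lags_ms, 180, 45, 0.6) + gauss_bump(lags_ms, 380, 80, -0.3),
    Et = gauss_bump(lags_ms, 210, 50, 0.45) + gauss_bump(lags_ms, 430, 85, -0.2),
    DBo = gauss_bump(lags_ms, 185, 40, 1.0) + gauss_bump(lags_ms, 650, 90, -0.6),
    DBcp = gauss_bump(lags_ms, 260, 60, dbcp_amp),
    DBcpt = gauss_bump(lags_ms, 185, 40, interaction)
  )
  k$DBct <- k$DBo
  w <- frontocentral_weights(channels)
  structure(list(kernels = k, channel_weights = w, lags = lags,
                 lags_ms = lags_ms, fs = fs),
            class = "kernel_bank")
}

frontocentral_weights <- function(channels) {
  base <- c(Fp1 = 0.55, Fp2 = 0.55, F7 = 0.45, F3 = 0.8, Fz = 1.0, F4 = 0.8,
            F8 = 0.45, FC5 = 0.6, FC1 = 0.95, FC2 = 0.95, FC6 = 0.6,
            T7 = 0.35, C3 = 0.75, Cz = 0.95, C4 = 0.75, T8 = 0.35,
            TP9 = 0.2, CP5 = 0.45, CP1 = 0.65, CP2 = 0.65, CP6 = 0.45,
            TP10 = 0.2, P7 = 0.25, P3 = 0.45, Pz = 0.5, P4 = 0.45,
            P8 = 0.25, PO9 = 0.15, O1 = 0.2, Oz = 0.2, O2 = 0.2, PO10 = 0.15)
  w <- base[channels]
  w[is.na(w)] <- 0.5
  names(w) <- channels
  w / max(w)
}

# y(t) = sum_l x(t - l) k(l) on the trial grid, zero-padded edges
conv_lagged <- function(x, kernel, lags) {
  n <- length(x)
  y <- numeric(n)
  for (j in seq_along(lags)) {
    if (kernel[j] == 0) next
    l <- lags[j]
    src <- seq_len(n) - l
    ok <- src >= 1L & src <= n
    y[ok] <- y[ok] + kernel[j] * x[src[ok]]
  }
  y
}

one_over_f_noise <- function(n, fs, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  shape <- 1 / pmax(f, 1)^(exponent / 2)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' Simulate one multichannel EEG trial
#'
#' Forward model of the TRF's generative assumption: the clean source is
#' the sum over regressors of the regressor convolved with its ground-truth
#' kernel, projected to channels by the frontocentral weight map; noise is
#' 1/f-shaped Gaussian with a shared component across channels (spatial
#' correlation ~0.3), scaled so the clean-to-noise variance ratio averaged
#' over channels equals the requested SNR in dB. `snr_db = Inf` yields
#' noiseless EEG.
#'
#' @param regs named list of regressor signals (or a [regressor_set()]);
#'   only names present in the kernel bank contribute.
#' @param kernels a [default_kernels()] bank (possibly rescaled).
#' @param snr_db signal-to-noise ratio in dB (default 0).
#' @param seed RNG seed for the noise.
#' @param spatial_rho shared-noise correlation across channels (default 0.3).
#' @return samples x channels matrix with attribute `"clean"` (the
#'   noiseless part).
#' @export
simulate_trial <- function(regs, kernels, snr_db = 0, seed = 1L,
                           spatial_rho = 0.3) {
  if (inherits(regs, "regressor_set")) regs <- regs$signals
  stopifnot(inherits(kernels, "kernel_bank"))
  use <- intersect(names(regs), names(kernels$kernels))
  n <- length(regs[[1]])
  src <- numeric(n)
  for (nm in use) src <- src + conv_lagged(regs[[nm]], kernels$kernels[[nm]],
                                           kernels$lags)
  w <- kernels$channel_weights
  clean <- outer(src, w)
  if (is.infinite(snr_db)) {
    eeg <- clean
  } else {
    noise <- with_seed(seed, {
      shared <- one_over_f_noise(n, kernels$fs)
      indep <- vapply(seq_along(w), function(i) one_over_f_noise(n, kernels$fs),
                      numeric(n))
      sqrt(1 - spatial_rho) * indep + sqrt(spatial_rho) * shared
    })
    v_clean <- mean(apply(clean, 2, stats::var))
    v_noise <- mean(apply(noise, 2, stats::var))
    if (v_clean > 0) noise <- noise * sqrt(v_clean / v_noise / 10^(snr_db / 10))
    eeg <- clean + noise
  }
  colnames(eeg) <- names(w)
  attr(eeg, "clean") <- clean
  eeg
}

#' Default configuration for a simulated study
#'
#' Desk-scale stand-in for a full listening study: a few stimulus sets of
#' equal-note-count cross-group pairs, ~30 s apiece, heard by every subject;
#' per-subject musicianship-linked onset-kernel gain; expectation kernels
#' attenuated for chimeric trials.
#'
#' @param n_sets stimulus sets (each contributes 4 trials: 2 original, 2
#'   chimeric).
#' @param n_subjects simulated subjects.
#' @param n_notes notes per melody.
#' @param quarter_s quarter-note duration in seconds.
#' @param fs EEG grid rate.
#' @param n_channels channels (first `n_channels` of the montage).
#' @param snr_db per-trial SNR.
#' @param chimeric_attenuation multiplier on the expectation kernels for
#'   chimeric trials (default 0.5: a weakened expectation response).
#' @param musicianship_gain onset-kernel gain per year of training
#'   (default 0.08).
#' @param interaction DBcpt kernel amplitude (default 0).
#' @param expectation_scale global multiplier on the expectation kernels
#'   (default 1; set 0 to generate from the acoustic + downbeat model only,
#'   the appropriate null for downbeat-estimator checks).
#' @param lag_window_ms analysis/generation lag window (default
#'   `c(-100, 800)`).
#' @param order_bound expectation-model order bound.
#' @param ltm_corpus_size melodies in the long-term training corpus.
#' @param with_flux include the rendered-audio spectral-flux regressor
#'   (default `TRUE`).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_sets = 3L, n_subjects = 10L, n_notes = 60L,
                       quarter_s = 0.45, fs = 125, n_channels = 32L,
                       snr_db = 0, chimeric_attenuation = 0.5,
                       musicianship_gain = 0.08, interaction = 0,
                       expectation_scale = 1,
                       lag_window_ms = c(-100, 800), order_bound = 10L,
                       ltm_corpus_size = 6L, with_flux = TRUE) {
  structure(as.list(environment()), class = "sim_config")
}

scale_kernels <- function(bank, which, gain) {
  for (nm in which) bank$kernels[[nm]] <- bank$kernels[[nm]] * gain
  bank
}

pad_to <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

build_trial_regressors <- function(seqs, masks, cfg, ltm) {
  lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    dur <- sequence_duration(s)
    feats <- sequence_expectations(s, ltm$pitch, ltm$ioi,
                                   order_bound = cfg$order_bound)
    regs <- c(
      list(onset = impulse_train(s, fs = cfg$fs, duration_s = dur)),
      expectation_regressors(s, feats, fs = cfg$fs, duration_s = dur)
    )
    if (cfg$with_flux) {
      wav <- render_tones(s)
      regs <- c(list(flux = pad_to(spectral_flux(wav, fs_out = cfg$fs),
                                   length(regs$onset))), regs)
    }
    c(regs, masks[[i]](s, dur))
  })
}

#' Simulate a full chimeric-music study
#'
#' Generates cross-group stimulus-set pairs (equal note counts), their
#' chimeric fusions, per-trial regressor sets (acoustic, expectation, and
#' downbeat impulse trains), ground-truth kernels with per-subject
#' musicianship-linked gains and chimeric expectation attenuation, and
#' simulated EEG for every subject x trial. Fully reproducible from
#' (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed study-level RNG seed.
#' @return list of class `sim_study`: `config`, `seed`, `sets`,
#'   `manifest` (trial, stimset, category, label), `regressors` (per
#'   trial), `kernels` (base bank), `subjects` (data.frame with
#'   `musicianship_years`, `onset_gain`), `eeg` (list: subject -> trial ->
#'   samples x channels matrix), `lags`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  lags <- lag_samples(cfg$lag_window_ms[1], cfg$lag_window_ms[2], cfg$fs)
  channels <- montage_adjacency()$channels[seq_len(cfg$n_channels)]
  bank <- default_kernels(cfg$fs, lags, channels, interaction = cfg$interaction)
  bank <- scale_kernels(bank, c("Sp", "Ep", "St", "Et"), cfg$expectation_scale)

  n_trials <- cfg$n_sets * 4L
  seeds <- with_seed(seed, sample.int(2^31 - 2, cfg$n_sets * 2 + cfg$ltm_corpus_size +
                                        1 + cfg$n_subjects * n_trials + 8))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  # stimulus sets: one triple + one duple piece of equal note count
  sets <- lapply(seq_len(cfg$n_sets), function(k) {
    p1 <- generate_melody(c(3L, 4L), cfg$n_notes, cfg$quarter_s, next_seed(),
                          label = sprintf("tri%02d", k))
    p2 <- generate_melody(c(4L, 4L), cfg$n_notes, cfg$quarter_s, next_seed(),
                          label = sprintf("dup%02d", k))
    build_stimulus_set(p1, p2)
  })

  ltm_corpus <- lapply(seq_len(cfg$ltm_corpus_size), function(k)
    generate_melody(if (k %% 2) c(3L, 4L) else c(4L, 4L), cfg$n_notes,
                    cfg$quarter_s, next_seed()))
  ltm <- list(
    pitch = ngram_train(lapply(ltm_corpus, function(s) viewpoints(s)$pitch_seq),
                        cfg$order_bound),
    ioi = ngram_train(lapply(ltm_corpus, function(s)
      quantize_ioi(viewpoints(s)$ioi_seq)), cfg$order_bound)
  )

  mask_of <- function(s) annotate_downbeats(s, cfg$quarter_s)
  seqs <- list(); masks <- list(); manifest <- NULL
  for (k in seq_along(sets)) {
    st <- sets[[k]]
    m1 <- mask_of(st$original_1); m2 <- mask_of(st$original_2)
    add <- function(s, cat, db_builder) {
      seqs[[length(seqs) + 1L]] <<- s
      masks[[length(masks) + 1L]] <<- db_builder
      manifest <<- rbind(manifest, data.frame(
        trial = length(seqs), stimset = k, category = cat, label = s$label))
    }
    add(st$original_1, "original", function(s, dur)
      downbeat_regressors_original(s, m1, cfg$fs, dur)["DBo"])
    add(st$original_2, "original", function(s, dur)
      downbeat_regressors_original(s, m2, cfg$fs, dur)["DBo"])
    add(st$chimeric_a, "chimeric", function(s, dur)
      downbeat_regressors_chimeric(s, m1, m2, cfg$fs, dur)[c("DBct", "DBcp", "DBcpt")])
    add(st$chimeric_b, "chimeric", function(s, dur)
      downbeat_regressors_chimeric(s, m2, m1, cfg$fs, dur)[c("DBct", "DBcp", "DBcpt")])
  }
  regressors <- build_trial_regressors(seqs, masks, cfg, ltm)

  subjects <- with_seed(next_seed(), data.frame(
    subject = seq_len(cfg$n_subjects),
    musicianship_years = stats::runif(cfg$n_subjects, 0, 11)))
  subjects$onset_gain <- 1 + cfg$musicianship_gain * subjects$musicianship_years

  expect_feats <- c("Sp", "Ep", "St", "Et")
  eeg <- lapply(seq_len(cfg$n_subjects), function(s) {
    sub_bank <- scale_kernels(bank, "onset", subjects$onset_gain[s])
    lapply(seq_along(regressors), function(tr) {
      b <- if (manifest$category[tr] == "chimeric")
        scale_kernels(sub_bank, expect_feats, cfg$chimeric_attenuation)
      else sub_bank
      simulate_trial(regressors[[tr]], b, cfg$snr_db, seed = next_seed())
    })
  })

  structure(list(config = cfg, seed = seed, sets = sets, manifest = manifest,
                 regressors = regressors, kernels = bank, subjects = subjects,
                 eeg = eeg, lags = lags, channels = channels, ltm = ltm),
            class = "sim_study")
}

#' Cross-validated accuracy table for a simulated study
#'
#' Fits the acoustic baseline (A) and expectation (AM, and optionally AMp /
#' AMt) ridge TRF models per subject with leave-one-out cross-validation
#' and returns the long-format accuracy table consumed by
#' [delta_r_table()].
#'
#' @param study a [simulate_study()] result.
#' @param models character subset of `c("A", "AM", "AMp", "AMt")`.
#' @param lambda_grid ridge grid for [loo_crossval()].
#' @param lags integer analysis lags in samples (default: the study's
#'   generation lag grid; a shorter window speeds up fitting).
#' @return data.frame with columns `participant`, `stimset`,
#'   `stim_category`, `model_tag`, `r`, `musicianship_years`, `preference`.
#' @export
study_accuracy_table <- function(study, models = c("A", "AM"),
                                 lambda_grid = 10^(-3:3), lags = study$lags) {
  cfg <- study$config
  feat_sets <- list(A = c("flux", "onset"),
                    AM = c("flux", "onset", "Sp", "Ep", "St", "Et"),
                    AMp = c("flux", "onset", "Sp", "Ep"),
                    AMt = c("flux", "onset", "St", "Et"))
  if (!cfg$with_flux) feat_sets <- lapply(feat_sets, setdiff, "flux")
  full <- unique(unlist(feat_sets[models]))
  L <- length(lags)

  # Gram matrices on the full feature set, computed once per trial and
  # shared across subjects and models (model designs are column subsets)
  Sxx_full <- list(); n_list <- list()
  Sxy_full <- lapply(seq_len(cfg$n_subjects), function(s) vector("list", 0))
  yss_full <- Sxy_full
  for (tr in seq_along(study$regressors)) {
    D <- lagged_design(study$regressors[[tr]][full], lags)
    D <- sweep(D, 2, colMeans(D))
    Sxx_full[[tr]] <- crossprod(D)
    n_list[[tr]] <- nrow(D)
    for (s in seq_len(cfg$n_subjects)) {
      Y <- sweep(study$eeg[[s]][[tr]], 2, colMeans(study$eeg[[s]][[tr]]))
      Sxy_full[[s]][[tr]] <- crossprod(D, Y)
      yss_full[[s]][[tr]] <- colSums(Y^2)
    }
  }

  rows <- NULL
  for (m in models) {
    cols <- as.vector(outer(seq_len(L), (match(feat_sets[[m]], full) - 1L) * L, `+`))
    r_arr <- loo_eval_multi(
      lapply(Sxx_full, function(S) S[cols, cols, drop = FALSE]),
      n_list,
      lapply(Sxy_full, function(l) lapply(l, function(S) S[cols, , drop = FALSE])),
      yss_full, lambda_grid, standardize = TRUE)
    for (s in seq_len(cfg$n_subjects)) {
      best <- which.max(colMeans(matrix(r_arr[s, , ], dim(r_arr)[2])))
      r_trial <- r_arr[s, , best]
      agg <- stats::aggregate(r_trial,
                              by = list(stimset = study$manifest$stimset,
                                        stim_category = study$manifest$category),
                              FUN = mean)
      rows <- rbind(rows, data.frame(
        participant = s, stimset = agg$stimset, stim_category = agg$stim_category,
        model_tag = m, r = agg$x,
        musicianship_years = study$subjects$musicianship_years[s],
        preference = NA_real_))
    }
  }
  rows
}
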