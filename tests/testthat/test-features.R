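test_that("impulse trains bin onsets with round-half-up and conserve counts", {
  m <- make_seq(c(60, 62), onsets = c(0, 0.5), dur = c(0.4, 0.4))
  x <- impulse_train(m, fs = 125, duration_s = 1)
  expect_identical(which(x != 0), c(1L, 64L))   # 0.5 * 125 = 62.5 -> sample 63 (0-based)
  expect_equal(sum(x), 2)

  zero <- impulse_train(m, mask = c(FALSE, FALSE), fs = 125, duration_s = 1)
  expect_true(all(zero == 0))

  set.seed(3)
  mel <- generate_melody(c(4L, 4L), 30, seed = 9)
  expect_equal(sum(impulse_train(mel)), 30)

  # collision: two notes in one 8 ms bin
  clash <- note_sequence(c(0, 0.002), c(0.1, 0.1), c(60, 62))
  expect_error(impulse_train(clash), "one sample")
})

test_that("scaled impulse trains carry per-note amplitudes", {
  m <- make_seq(c(60, 62), onsets = c(0, 0.5))
  x <- scaled_impulse_train(m, c(1.0, 2.0), fs = 125, duration_s = 1)
  expect_equal(sort(x[x != 0]), c(1, 2))
  expect_equal(scaled_impulse_train(m, c(1, 1), fs = 125, duration_s = 1),
               impulse_train(m, fs = 125, duration_s = 1))
  expect_error(scaled_impulse_train(m, 1), "length")
})

test_that("downbeat regressors satisfy subset and interaction invariants", {
  mel <- generate_melody(c(3L, 4L), 36, seed = 5)
  mask <- annotate_downbeats(mel, quarter_s = 0.45)
  regs <- downbeat_regressors_original(mel, mask)
  expect_equal(sum(regs$DBo), sum(mask$is_downbeat))
  expect_true(all(which(regs$DBo != 0) %in% which(regs$onset != 0)))

  # degenerate masks
  all_db <- downbeat_regressors_original(mel, rep(TRUE, length(mel)))
  expect_equal(all_db$DBo, all_db$onset)
  no_db <- downbeat_regressors_original(mel, rep(FALSE, length(mel)))
  expect_true(all(no_db$DBo == 0))
})

test_that("chimeric downbeat trains decouple pitch and time sources", {
  # toy pair: pitch-source downbeats at notes 1 and 6, time-source at 1 and 8
  chim <- make_seq(60:69, ioi = 0.4)
  mp <- c(TRUE, rep(FALSE, 4), TRUE, rep(FALSE, 4))
  mt <- c(TRUE, rep(FALSE, 6), TRUE, FALSE, FALSE)
  regs <- downbeat_regressors_chimeric(chim, mp, mt)
  on_idx <- which(regs$onset != 0)
  expect_identical(which(regs$DBcp != 0), on_idx[c(1, 6)])
  expect_identical(which(regs$DBct != 0), on_idx[c(1, 8)])
  expect_identical(which(regs$DBcpt != 0), on_idx[1])
  expect_equal(regs$DBcpt, pmin(regs$DBcp, regs$DBct))

  same <- downbeat_regressors_chimeric(chim, mp, mp)
  expect_equal(same$DBcp, same$DBct)
  expect_equal(same$DBcp, same$DBcpt)

  disjoint <- downbeat_regressors_chimeric(chim, c(FALSE, mp[-1]), mt)
  expect_true(all(disjoint$DBcpt == 0))

  expect_error(downbeat_regressors_chimeric(chim, mp[1:5], mt), "shorter")
})

test_that("regressor_set validates lengths and the subset invariant", {
  ok <- regressor_set(list(onset = c(0, 1, 0, 1), DBo = c(0, 1, 0, 0)))
  expect_s3_class(ok, "regressor_set")
  expect_error(regressor_set(list(onset = c(0, 1), DBo = c(0, 1, 0))), "length")
  expect_error(regressor_set(list(onset = c(0, 1, 0, 0), DBo = c(0, 1, 1, 0))),
               "subset")
})

test_that("rendered tones honour MIDI tuning and RMS normalization", {
  one <- note_sequence(0, 0.5, 69)
  wav <- render_tones(one)
  expect_equal(sqrt(mean(wav^2)), 0.01, tolerance = 1e-6)
  # fundamental at 440 Hz: spectral peak of the first harmonic
  n <- length(wav)
  spec <- Mod(fft(wav))[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * 48000 / n
  expect_lt(abs(f[which.max(spec)] - 440), 5)
  expect_error(render_tones(note_sequence(numeric(0), numeric(0), integer(0))),
               "empty")
})

test_that("spectral flux localizes onsets and z-scores the trial", {
  m <- note_sequence(c(0.2, 1.0), c(0.3, 0.3), c(69, 69))
  wav <- render_tones(m, decay_s = 0.05)
  flux <- spectral_flux(wav, fs_out = 125)
  expect_equal(mean(flux), 0, tolerance = 1e-8)
  # peak within one frame (~11 ms at 48 kHz / 512 hop) of the second onset
  t_axis <- (seq_along(flux) - 1) / 125
  peaks <- order(flux, decreasing = TRUE)[1:6]
  expect_true(any(abs(t_axis[peaks] - 1.0) <= 0.025))
  expect_true(any(abs(t_axis[peaks] - 0.2) <= 0.025))

  # two equal-amplitude onsets give flux peaks equal within 5%
  p1 <- max(flux[t_axis > 0.1 & t_axis < 0.5])
  p2 <- max(flux[t_axis > 0.9 & t_axis < 1.3])
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.05)

  expect_warning(z <- spectral_flux(numeric(48000)), "silent")
  expect_true(all(z == 0))
})
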