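test_that("training counts match hand counts", {
  m <- ngram_train(list(c("A", "B", "A", "B")), order_bound = 1L)
  counts_of <- function(model, ctx) {
    tab <- model$counts[[chimeraTRF:::ctx_key(ctx)]]
    if (is.null(tab)) return(integer(0))
    vapply(ls(tab), function(s) tab[[s]], 0L)
  }
  expect_identical(counts_of(m, "A"), c(B = 2L))
  expect_identical(counts_of(m, "B"), c(A = 1L))
  expect_identical(sort(counts_of(m, character(0))), c(A = 2L, B = 2L))

  empty <- ngram_train(list(), order_bound = 2L)
  expect_identical(empty$alphabet, character(0))

  runs <- ngram_train(list(c("A", "A", "A", "A")), order_bound = 1L)
  expect_identical(counts_of(runs, "A"), c(A = 3L))
})

test_that("prediction falls back to uniform and truncates long contexts", {
  empty <- ngram_train(list(), order_bound = 2L)
  p <- ngram_predict(empty, character(0), LETTERS[1:4])
  expect_equal(unname(p), rep(0.25, 4))

  m <- ngram_train(list(c("A", "B", "A", "B")), order_bound = 1L)
  # PPM-C interpolated arithmetic by hand: order 0 gives 1/2 each;
  # after "A": counts {B: 2}, n = 2, t = 1 -> P(B|A) = 2/3 + 1/3 * 1/2 = 5/6
  p2 <- ngram_predict(m, "A", c("A", "B"))
  expect_equal(p2[["B"]], 5 / 6, tolerance = 1e-12)
  expect_equal(p2[["A"]], 1 / 6, tolerance = 1e-12)

  # context longer than order_bound: identical to the truncated context
  expect_equal(ngram_predict(m, c("B", "B", "A"), c("A", "B")), p2)
})

test_that("predicted distributions equal the brute-force escape oracle", {
  set.seed(7)
  for (case in 1:25) {
    K <- sample(2:5, 1)
    alphabet <- LETTERS[1:K]
    order_bound <- sample(0:2, 1)
    corpus <- lapply(seq_len(sample(1:3, 1)), function(i)
      sample(alphabet, sample(3:20, 1), replace = TRUE))
    m <- ngram_train(corpus, order_bound)
    for (j in 1:4) {
      context <- sample(alphabet, sample(0:3, 1), replace = TRUE)
      got <- ngram_predict(m, context, alphabet)
      want <- oracle_predict(corpus, order_bound, context, alphabet)
      expect_equal(got, want[names(got)], tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-9)
      expect_true(all(got > 0))
    }
  }
})

test_that("surprisal and entropy match closed forms", {
  u <- rep(0.25, 4); names(u) <- LETTERS[1:4]
  se <- info_measures(u, "B")
  expect_equal(se[["S"]], log(4))
  expect_equal(se[["E"]], log(4))

  degenerate <- c(A = 1)
  expect_equal(unname(info_measures(degenerate, "A")), c(0, 0))

  p <- c(A = 0.5, B = 0.25, C = 0.25)
  se2 <- info_measures(p, "A")
  expect_equal(se2[["S"]], log(2), tolerance = 1e-12)
  expect_equal(se2[["E"]], 1.5 * log(2), tolerance = 1e-12)

  expect_error(info_measures(p, "Z"), "not in alphabet")
})

test_that("entropy is bounded by log alphabet size on random predictions", {
  set.seed(11)
  m <- ngram_train(list(sample(LETTERS[1:4], 30, replace = TRUE)), 2L)
  for (i in 1:20) {
    ctx <- sample(LETTERS[1:4], sample(0:2, 1), replace = TRUE)
    p <- ngram_predict(m, ctx, LETTERS[1:4])
    E <- -sum(p * log(p))
    expect_gte(E, 0)
    expect_lte(E, log(4) + 1e-12)
  }
})

test_that("STM/LTM combination respects entropy weighting", {
  peaked <- c(A = 0.9, B = 0.05, C = 0.05)
  unif <- c(A = 1, B = 1, C = 1) / 3

  # idempotence
  expect_equal(combine_dists(peaked, peaked), peaked, tolerance = 1e-12)

  # hand computation for the peaked/uniform pair, |K| = 3, geometric, b = 1
  h_peak <- -sum(peaked * log(peaked)) / log(3)
  w <- c(1 / h_peak, 1 / 1); w <- w / sum(w)
  byhand <- exp(w[1] * log(peaked) + w[2] * log(unif))
  byhand <- byhand / sum(byhand)
  got <- combine_dists(peaked, unif)
  expect_equal(got, byhand, tolerance = 1e-12)
  # output closer to the peaked source than the arithmetic midpoint
  expect_gt(got[["A"]], mean(c(peaked[["A"]], unif[["A"]])))

  # forced weights reduce to one source
  expect_equal(combine_dists(peaked, unif, weights = c(1, 0)), peaked,
               tolerance = 1e-12)
  expect_equal(combine_dists(peaked, unif, weights = c(0, 1), mode = "arithmetic"),
               unif, tolerance = 1e-12)

  expect_error(combine_dists(peaked, c(A = 0.5, D = 0.5)), "alphabet mismatch")
})

test_that("IOI quantization maps to grid multiples and flags off-grid values", {
  expect_identical(quantize_ioi(c(0.25, 0.5, 0.75, 0.25)), c("1", "2", "3", "1"))
  expect_warning(quantize_ioi(c(0.25, 0.41)), "quantization grid")
  expect_identical(quantize_ioi(c(0.3, 0.6), unit_s = 0.3), c("1", "2"))
})

test_that("sequence expectations reduce to the static model in LTM mode", {
  ltm_p <- ngram_train(list(as.character(c(60, 62, 64, 62, 60))), 2L)
  ltm_i <- ngram_train(list(c("1", "2", "1", "1")), 2L)
  m <- make_seq(c(60, 62, 64, 62), ioi = 0.25)
  got <- sequence_expectations(m, ltm_p, ltm_i, mode = "ltm")

  vp <- viewpoints(m)
  alphabet <- union(ltm_p$alphabet, as.character(vp$pitch_seq))
  want_S <- vapply(seq_along(vp$pitch_seq), function(t) {
    ctx <- as.character(vp$pitch_seq)[seq_len(t - 1)]
    -log(ngram_predict(ltm_p, ctx, alphabet)[[as.character(vp$pitch_seq[t])]])
  }, 0)
  expect_equal(got$Sp, want_S, tolerance = 1e-12)
  expect_true(is.na(got$St[1]))
  expect_length(got$St, 4L)
})

test_that("repetition drives short-term surprisal down", {
  m <- make_seq(rep(c(60, 64), 6), ioi = 0.25)
  feats <- sequence_expectations(m, mode = "stm", order_bound = 1L)
  # surprisal of successive 64-after-60 events strictly decreases
  b_events <- seq(2, 12, by = 2)
  sp <- feats$Sp[b_events]
  expect_true(all(diff(sp[1:4]) < 0))
  expect_true(all(feats$Sp >= 0))
  expect_true(all(feats$Ep >= 0))
})
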