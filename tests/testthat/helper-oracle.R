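# Shared fixtures and independent oracles used across test files.

# quick melody builder: isochronous unless onsets given
make_seq <- function(pitches, ioi = 0.5, ts = c(4L, 4L), onsets = NULL,
                     dur = NULL, label = "fixture") {
  n <- length(pitches)
  if (is.null(onsets)) onsets <- (seq_len(n) - 1) * ioi
  if (is.null(dur)) dur <- rep(if (is.null(ioi)) 0.4 else ioi * 0.8, n)
  note_sequence(onsets, dur, pitches, ts, label = label)
}

# Independent PPM escape-method-C oracle: recursive interpolated smoothing
# computed by direct corpus scanning, sharing no code with the package.
oracle_counts_after <- function(corpus, ctx) {
  k <- length(ctx)
  syms <- character(0)
  for (s in corpus) {
    s <- as.character(s)
    for (t in seq_along(s)) {
      if (t - 1 < k) next
      if (k == 0 || all(s[(t - k):(t - 1)] == ctx)) syms <- c(syms, s[t])
    }
  }
  syms
}

oracle_predict <- function(corpus, order_bound, context, alphabet) {
  context <- as.character(context)
  rec <- function(k) {
    if (k < 0) {
      p <- rep(1 / length(alphabet), length(alphabet))
      names(p) <- alphabet
      return(p)
    }
    ctx <- if (k == 0) character(0) else utils::tail(context, k)
    occ <- oracle_counts_after(corpus, ctx)
    n <- length(occ)
    if (n == 0) return(rec(k - 1))
    t_esc <- length(unique(occ))
    lower <- rec(k - 1)
    p <- vapply(alphabet, function(s) sum(occ == s), 0) / (n + t_esc) +
      (t_esc / (n + t_esc)) * lower
    p / sum(p)
  }
  rec(min(order_bound, length(context)))
}

# independent step-down Holm adjustment
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent step-up Benjamini-Hochberg adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(cummin(m / (m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
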