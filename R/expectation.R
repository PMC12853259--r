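# Variable-order n-gram melodic expectation (IDyOM-family modelling).
#
# Contexts and symbols are stored as character keys in nested environments
# (hash maps): counts[[context_key]][[symbol]] -> count. Prediction uses
# PPM-style interpolated smoothing with escape method C:
#
#   P_k(s | ctx_k) = c(ctx_k, s) / (n_k + t_k)  +  t_k / (n_k + t_k) * P_{k-1}(s)
#
# where n_k is the total count after ctx_k, t_k the number of distinct
# symbols seen after ctx_k, and the recursion bottoms out at the uniform
# distribution over the supplied alphabet. An unseen context contributes
# nothing (P_k = P_{k-1}), so every prediction is strictly positive and the
# probabilities sum to one.

CTX_SEP <- "\u001f"  # unit separator: never occurs in pitch/IOI symbols
# "|" prefix keeps the empty-context key a legal environment variable name
ctx_key <- function(context) paste0("|", paste(context, collapse = CTX_SEP))

empty_ngram <- function(order_bound) {
  structure(list(order_bound = as.integer(order_bound),
                 counts = new.env(parent = emptyenv()),
                 alphabet = character(0),
                 smoothing = "ppm_c_interpolated"),
            class = "ngram_model")
}

add_count <- function(model, context, symbol) {
  key <- ctx_key(context)
  tab <- model$counts[[key]]
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    assign(key, tab, envir = model$counts)
  }
  prev <- tab[[symbol]]
  assign(symbol, if (is.null(prev)) 1L else prev + 1L, envir = tab)
  invisible(model)
}

#' Train a variable-order n-gram model
#'
#' Counts every (context, next symbol) pair for all context lengths
#' 0..`order_bound` over a corpus of symbol sequences. Symbols are coerced to
#' character, so any discrete viewpoint (MIDI pitch, quantized IOI class)
#' can be modelled.
#'
#' @param sequences list of symbol vectors (each a training sequence); may be
#'   empty for a model that starts untrained (the short-term model does).
#' @param order_bound maximum context length (n-gram order minus one);
#'   default 10 with longest-match back-off.
#' @return an object of class `ngram_model`.
#' @examples
#' m <- ngram_train(list(c("A", "B", "A", "B")), order_bound = 1)
#' ngram_predict(m, "A", c("A", "B"))  # P(B|A) = 5/6
#' @export
ngram_train <- function(sequences, order_bound = 10L) {
  if (order_bound < 0L) stop("order_bound must be >= 0")
  model <- empty_ngram(order_bound)
  for (s in sequences) {
    s <- as.character(s)
    for (t in seq_along(s)) {
      for (k in 0:min(order_bound, t - 1L)) {
        context <- if (k == 0L) character(0) else s[(t - k):(t - 1L)]
        add_count(model, context, s[t])
      }
    }
    model$alphabet <- union(model$alphabet, s)
  }
  model
}

#' Update a model with one observed symbol
#'
#' Online learning step used by the short-term model: inserts the counts for
#' `symbol` after every suffix of `context` up to the order bound.
#'
#' @param model an `ngram_model`.
#' @param context the symbols preceding the observation (full history; only
#'   the last `order_bound` are used).
#' @param symbol the observed symbol.
#' @return the updated model (environments are mutated in place; the return
#'   value carries the updated alphabet).
#' @export
ngram_update <- function(model, context, symbol) {
  context <- as.character(context)
  symbol <- as.character(symbol)
  nc <- length(context)
  for (k in 0:min(model$order_bound, nc)) {
    ctx <- if (k == 0L) character(0) else context[(nc - k + 1L):nc]
    add_count(model, ctx, symbol)
  }
  model$alphabet <- union(model$alphabet, symbol)
  model
}

#' Predict the next-symbol distribution
#'
#' PPM escape-method-C prediction with interpolated back-off: starting from
#' the longest stored suffix of `context` (at most `order_bound` symbols),
#' each level contributes its maximum-likelihood mass and escapes with
#' probability t/(n+t) to the next shorter context, bottoming out at the
#' uniform distribution over `alphabet`. The result is strictly positive on
#' the whole alphabet and sums to one.
#'
#' @param model an `ngram_model`.
#' @param context preceding symbols (may be longer than the order bound; only
#'   the final `order_bound` symbols matter).
#' @param alphabet symbol alphabet K over which to predict (usually the union
#'   of the model alphabet and the stimulus alphabet); nonempty.
#' @return named numeric vector of probabilities over `alphabet`.
#' @export
ngram_predict <- function(model, context, alphabet) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0L) stop("alphabet must be nonempty")
  context <- as.character(context)
  nc <- length(context)
  kmax <- min(model$order_bound, nc)

  p <- rep(1 / length(alphabet), length(alphabet))
  names(p) <- alphabet
  for (k in 0:kmax) {      # from shortest to longest context
    ctx <- if (k == 0L) character(0) else context[(nc - k + 1L):nc]
    tab <- model$counts[[ctx_key(ctx)]]
    if (is.null(tab)) next
    syms <- ls(tab)
    cnt <- vapply(syms, function(s) tab[[s]], 0L)
    n <- sum(cnt); t <- length(syms)
    if (n == 0L) next
    p <- (t / (n + t)) * p
    seen <- intersect(syms, alphabet)
    p[seen] <- p[seen] + cnt[seen] / (n + t)
  }
  p / sum(p)
}

#' Surprisal and entropy of an observation
#'
#' Given the predicted distribution before a note and the symbol actually
#' observed, returns the surprisal `S = -ln P(observed)` (the unexpectedness
#' of the note) and the entropy `E = sum_x P(x) * (-ln P(x))` (the
#' uncertainty of the context before the note). Natural logarithm: values
#' are in nats.
#'
#' @param dist named probability vector (a prediction from
#'   [ngram_predict()] or [combine_dists()]).
#' @param observed the observed symbol; must be in the alphabet of `dist`.
#' @return named numeric `c(S = ..., E = ...)`.
#' @export
info_measures <- function(dist, observed) {
  observed <- as.character(observed)
  if (!observed %in% names(dist)) stop("observed symbol not in alphabet")
  c(S = -log(dist[[observed]]), E = -sum(dist * log(dist)))
}

#' Combine short-term and long-term predictions
#'
#' Merges two distributions over the same alphabet with entropy weighting:
#' each source's weight is proportional to `(1 / relative entropy)^bias`,
#' where relative entropy is its entropy divided by `ln |K|`, so the more
#' certain source dominates. Geometric combination (weighted geometric mean,
#' renormalized) is the default; arithmetic mixing is available.
#'
#' @param stm_dist,ltm_dist named probability vectors over the same alphabet.
#' @param bias exponent b of the entropy weighting (default 1).
#' @param mode `"geometric"` (default) or `"arithmetic"`.
#' @param weights optional fixed `c(w_stm, w_ltm)` overriding the entropy
#'   weighting (need not be normalized).
#' @return named probability vector over the common alphabet.
#' @export
combine_dists <- function(stm_dist, ltm_dist, bias = 1,
                          mode = c("geometric", "arithmetic"), weights = NULL) {
  mode <- match.arg(mode)
  if (!setequal(names(stm_dist), names(ltm_dist)))
    stop("alphabet mismatch between distributions")
  ltm_dist <- ltm_dist[names(stm_dist)]
  K <- length(stm_dist)
  if (is.null(weights)) {
    if (K == 1L) {
      weights <- c(0.5, 0.5)
    } else {
      hrel <- function(p) max(-sum(p * log(p)) / log(K), 1e-12)
      weights <- c(hrel(stm_dist)^(-bias), hrel(ltm_dist)^(-bias))
    }
  }
  w <- weights / sum(weights)
  out <- if (mode == "geometric") {
    exp(w[1] * log(stm_dist) + w[2] * log(ltm_dist))
  } else {
    w[1] * stm_dist + w[2] * ltm_dist
  }
  out / sum(out)
}

#' Quantize inter-onset intervals to a discrete symbol alphabet
#'
#' Maps each IOI to the nearest integer multiple of a grid unit (default:
#' the minimum IOI in the sequence) so the time viewpoint becomes a finite
#' symbol set. A warning is emitted when an IOI is further than `tol`
#' (relative) from its grid point, indicating non-metrical timing.
#'
#' @param ioi_seq numeric IOIs in seconds, all positive.
#' @param unit_s grid unit in seconds (default `min(ioi_seq)`).
#' @param tol relative off-grid tolerance before warning (default 0.01).
#' @return character vector of grid multiples (e.g. `"1"`, `"2"`, `"3"`).
#' @export
quantize_ioi <- function(ioi_seq, unit_s = min(ioi_seq), tol = 0.01) {
  stopifnot(all(ioi_seq > 0), unit_s > 0)
  mult <- pmax(1L, as.integer(round(ioi_seq / unit_s)))
  off <- abs(ioi_seq - mult * unit_s) / ioi_seq
  if (any(off > tol))
    warning(sum(off > tol), " IOI(s) further than ", tol,
            " (relative) from the quantization grid")
  as.character(mult)
}

predict_one <- function(stm, ltm, context, alphabet, mode, bias, comb_mode) {
  switch(mode,
    stm = ngram_predict(stm, context, alphabet),
    ltm = ngram_predict(ltm, context, alphabet),
    both = combine_dists(ngram_predict(stm, context, alphabet),
                         ngram_predict(ltm, context, alphabet),
                         bias = bias, mode = comb_mode)
  )
}

viewpoint_expectations <- function(symbols, ltm, order_bound, mode, bias,
                                   comb_mode) {
  symbols <- as.character(symbols)
  alphabet <- union(ltm$alphabet, unique(symbols))
  stm <- empty_ngram(order_bound)
  S <- E <- numeric(length(symbols))
  for (t in seq_along(symbols)) {
    context <- if (t == 1L) character(0) else symbols[seq_len(t - 1L)]
    dist <- predict_one(stm, ltm, context, alphabet, mode, bias, comb_mode)
    se <- info_measures(dist, symbols[t])
    S[t] <- se[["S"]]; E[t] <- se[["E"]]
    stm <- ngram_update(stm, context, symbols[t])
  }
  list(S = S, E = E)
}

#' Per-note expectation features of a melody
#'
#' Runs the expectation model over both viewpoints of a melody and returns
#' the four note-level features: pitch surprisal (Sp), pitch entropy (Ep),
#' time surprisal (St) and time entropy (Et), in nats. The short-term model
#' is trained online on the current piece (each note is predicted before it
#' is learned); the long-term models are static, trained on a corpus.
#' IOI features are aligned to notes 2..n (the first note has no IOI).
#'
#' @param seq a [note_sequence()] (or the list returned by [viewpoints()]).
#' @param ltm_pitch,ltm_ioi long-term `ngram_model`s for the pitch and
#'   quantized-IOI viewpoints; pass models trained on an empty corpus for
#'   STM-only use.
#' @param mode `"both"` (default), `"stm"` or `"ltm"`.
#' @param order_bound short-term model order bound (default 10).
#' @param bias entropy-weighting exponent for the "both" combination.
#' @param comb_mode `"geometric"` or `"arithmetic"` combination.
#' @param ioi_unit_s IOI quantization unit (default: minimum IOI of the
#'   piece); corpus and stimulus must share a unit for the LTM to transfer.
#' @return data.frame with columns `note`, `Sp`, `Ep`, `St`, `Et`; `St` and
#'   `Et` are `NA` for note 1.
#' @export
sequence_expectations <- function(seq, ltm_pitch = ngram_train(list()),
                                  ltm_ioi = ngram_train(list()),
                                  mode = c("both", "stm", "ltm"),
                                  order_bound = 10L, bias = 1,
                                  comb_mode = "geometric", ioi_unit_s = NULL) {
  mode <- match.arg(mode)
  vp <- if (inherits(seq, "note_sequence")) viewpoints(seq) else seq
  pitch_sym <- as.character(vp$pitch_seq)
  ioi_sym <- quantize_ioi(vp$ioi_seq,
                          unit_s = if (is.null(ioi_unit_s)) min(vp$ioi_seq)
                                   else ioi_unit_s)
  p <- viewpoint_expectations(pitch_sym, ltm_pitch, order_bound, mode, bias,
                              comb_mode)
  t <- viewpoint_expectations(ioi_sym, ltm_ioi, order_bound, mode, bias,
                              comb_mode)
  n <- length(pitch_sym)
  data.frame(note = seq_len(n),
             Sp = p$S, Ep = p$E,
             St = c(NA, t$S), Et = c(NA, t$E))
}
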