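# Statistical layer: prediction-accuracy contrasts, paired tests with
# Holm-Bonferroni correction, sign-flip permutation testing with TFCE over
# channel x lag maps, and peak-amplitude correlations with FDR control.

#' Template 10-20 montage adjacency
#'
#' Loads the shipped 32-channel 10-20 sensor neighbourhood graph (or a
#' user-supplied edge list with columns `from`, `to`).
#'
#' @param path edge-list TSV; default: the packaged template montage.
#' @return list with `channels` (character) and `edges` (two-column integer
#'   matrix of 1-based channel indices).
#' @export
montage_adjacency <- function(path = system.file("extdata", "montage_1020_32.tsv",
                                                 package = "chimeraTRF")) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  channels <- unique(c(el$from, el$to))
  edges <- cbind(match(el$from, channels), match(el$to, channels))
  list(channels = channels, edges = edges)
}

#' Expectation-effect table
#'
#' Computes the expectation effect Delta-r — the difference in
#' cross-validated prediction accuracy between each expectation model and
#' the acoustic baseline A — within each participant and stimulus set, in
#' the long format the mixed-model formulas consume (one row per
#' participant x category x contrast, plus any covariate columns).
#'
#' @param reports data.frame with one row per participant x stimulus set x
#'   category x model: columns `participant`, `stimset`, `stim_category`
#'   (`"original"`/`"chimeric"`), `model_tag` (must include `"A"`), `r`, and
#'   optionally covariates (e.g. `musicianship_years`, `preference`).
#' @return data.frame with columns `participant`, `stimset`,
#'   `stim_category`, `contrast` (e.g. `"AM-A"`), `delta_r` and the
#'   covariates.
#' @export
delta_r_table <- function(reports) {
  need <- c("participant", "stimset", "stim_category", "model_tag", "r")
  if (!all(need %in% names(reports)))
    stop("reports must have columns ", paste(need, collapse = ", "))
  key <- interaction(reports$participant, reports$stimset,
                     reports$stim_category, drop = TRUE)
  covars <- setdiff(names(reports), c(need))
  out <- lapply(split(reports, key), function(g) {
    a <- g[g$model_tag == "A", , drop = FALSE]
    others <- g[g$model_tag != "A", , drop = FALSE]
    if (nrow(a) != 1L || nrow(others) == 0L)
      stop("unmatched rows: each participant x stimset x category needs one ",
           "'A' row and at least one expectation-model row")
    cbind(others[, c("participant", "stimset", "stim_category"), drop = FALSE],
          contrast = paste0(others$model_tag, "-A"),
          delta_r = others$r - a$r,
          others[, covars, drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired t tests with Holm-Bonferroni correction
#'
#' Two-sided paired t tests for a set of named comparisons, with step-down
#' Holm adjustment of the p-values.
#'
#' @param comparisons named list; each element is a list or data.frame of
#'   two equal-length paired numeric vectors.
#' @param alpha family-wise level for the `reject` column (default 0.05).
#' @return data.frame with columns `comparison`, `t`, `df`, `p_raw`,
#'   `p_holm`, `reject`. Zero-variance differences yield `NA` p-values.
#' @export
paired_tests_holm <- function(comparisons, alpha = 0.05) {
  res <- lapply(names(comparisons), function(nm) {
    xy <- comparisons[[nm]]
    d <- xy[[1]] - xy[[2]]
    if (length(d) < 3L) stop("paired test needs n >= 3")
    if (stats::sd(d) == 0) {
      return(data.frame(comparison = nm, t = if (all(d == 0)) 0 else NA,
                        df = length(d) - 1L, p_raw = if (all(d == 0)) 1 else NA))
    }
    tt <- stats::t.test(xy[[1]], xy[[2]], paired = TRUE)
    data.frame(comparison = nm, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  })
  res <- do.call(rbind, res)
  res$p_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res$reject <- !is.na(res$p_holm) & res$p_holm < alpha
  res
}

spatiotemporal_edges <- function(n_chan, n_lag, chan_edges) {
  node <- function(ch, lg) (lg - 1L) * n_chan + ch   # lag-major layout
  e_sp <- NULL
  if (!is.null(chan_edges) && nrow(chan_edges) > 0) {
    if (any(chan_edges < 1L) || any(chan_edges > n_chan))
      stop("channel edge indices must lie in 1..", n_chan)
    lg <- rep(seq_len(n_lag), each = nrow(chan_edges))
    e_sp <- cbind(node(rep(chan_edges[, 1], n_lag), lg),
                  node(rep(chan_edges[, 2], n_lag), lg))
  }
  ch <- rep(seq_len(n_chan), n_lag - 1L)
  lg <- rep(seq_len(n_lag - 1L), each = n_chan)
  e_t <- cbind(node(ch, lg), node(ch, lg + 1L))
  rbind(e_sp, e_t)
}

#' Threshold-free cluster enhancement of a channel x lag map
#'
#' Integrates cluster extent and height over all thresholds:
#' `score(p) = sum_h extent_h(p)^E * h^H * dh` for `0 < h <= |t_p|`, with
#' clusters formed on the spatiotemporal graph linking neighbouring sensors
#' and consecutive lags. Positive and negative parts are enhanced
#' separately (two-sided use) and returned signed.
#'
#' @param stat_map numeric channels x lags matrix of t-values.
#' @param chan_edges two-column matrix of 1-based channel-neighbour indices
#'   (e.g. from [montage_adjacency()]); `NULL` for temporally-linked-only.
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh threshold step (default `max(abs(stat_map)) / 50`).
#' @return channels x lags matrix of signed TFCE scores.
#' @export
tfce <- function(stat_map, chan_edges = NULL, E = 0.5, H = 2,
                 dh = max(abs(stat_map)) / 50) {
  if (length(stat_map) == 0L) stop("empty statistic map")
  stat_map <- as.matrix(stat_map)
  if (all(stat_map == 0)) return(stat_map)
  edges <- spatiotemporal_edges(nrow(stat_map), ncol(stat_map), chan_edges)
  edges0 <- edges - 1L
  pos <- tfce_enhance_cpp(pmax(as.vector(stat_map), 0), edges0, E, H, dh)
  neg <- tfce_enhance_cpp(pmax(-as.vector(stat_map), 0), edges0, E, H, dh)
  matrix(pos - neg, nrow(stat_map), ncol(stat_map),
         dimnames = dimnames(stat_map))
}

one_sample_t_map <- function(X) {
  # X: subjects x points
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- 0
  t
}

#' Two-sided one-sample sign-flip permutation test with TFCE
#'
#' Tests a subjects x channels x lags effect array against zero. The
#' observed one-sample t map is TFCE-enhanced; the null distribution is the
#' maximum absolute TFCE score over the whole map for each of `n_perm`
#' subject-level sign flips (family-wise control), and per-point corrected
#' p-values are `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param data numeric array, subjects x channels x lags.
#' @param chan_edges channel-neighbour edge matrix (see [tfce()]).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param seed RNG seed for the flips.
#' @param alpha significance level recorded in the result (default 0.05).
#' @param E,H,dh TFCE parameters; `dh = NULL` uses `max |t| / 50`.
#' @return list of class `tfce_result`: `p_map` and `observed_tfce`
#'   (channels x lags), `t_map`, `null_max`, `n_permutations`, `seed`,
#'   `alpha`.
#' @export
signflip_permutation <- function(data, chan_edges = NULL, n_perm = 1000L,
                                 seed = 1L, alpha = 0.05, E = 0.5, H = 2,
                                 dh = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null distribution")
  ns <- dim(data)[1]; nc <- dim(data)[2]; nl <- dim(data)[3]
  X <- matrix(data, nrow = ns)            # subjects x (channel, lag) lag-major
  edges0 <- spatiotemporal_edges(nc, nl, chan_edges) - 1L

  tobs <- one_sample_t_map(X)
  dh_use <- if (is.null(dh)) max(abs(tobs)) / 50 else dh
  if (dh_use <= 0) dh_use <- 1   # all-zero map: scores stay zero
  enhance <- function(tv) {
    pmax(tfce_enhance_cpp(pmax(tv, 0), edges0, E, H, dh_use),
         tfce_enhance_cpp(pmax(-tv, 0), edges0, E, H, dh_use))
  }
  obs <- enhance(tobs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(p) {
    flips <- sample(c(-1, 1), ns, replace = TRUE)
    max(enhance(one_sample_t_map(flips * X)))
  }, 0)

  p <- vapply(obs, function(o) (1 + sum(null_max >= o)) / (1 + n_perm), 0)
  structure(list(p_map = matrix(p, nc, nl),
                 observed_tfce = matrix(obs, nc, nl),
                 t_map = matrix(tobs, nc, nl),
                 null_max = null_max,
                 n_permutations = n_perm, seed = seed, alpha = alpha),
            class = "tfce_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Peak-amplitude correlation with a covariate, FDR-corrected
#'
#' For each subject and channel, takes the maximum kernel amplitude inside a
#' lag window, correlates it across subjects with a covariate (e.g. years of
#' formal musical training), and applies Benjamini-Hochberg correction
#' across channels.
#'
#' @param kernels numeric array, subjects x channels x lags (one regressor's
#'   TRF weights).
#' @param lags_ms numeric lag axis in ms, length = dim 3.
#' @param window_ms `c(lo, hi)` window in which the peak is taken.
#' @param covariate numeric per subject; must not be constant.
#' @return data.frame with one row per channel: `channel`, `r`, `p`,
#'   `p_fdr`.
#' @export
peak_correlation_fdr <- function(kernels, lags_ms, window_ms, covariate) {
  stopifnot(length(dim(kernels)) == 3L, dim(kernels)[3] == length(lags_ms))
  if (stats::sd(covariate) == 0) stop("constant covariate")
  sel <- which(lags_ms >= window_ms[1] & lags_ms <= window_ms[2])
  if (length(sel) == 0L) stop("window outside lag range")
  nc <- dim(kernels)[2]
  res <- lapply(seq_len(nc), function(ch) {
    amp <- apply(kernels[, ch, sel, drop = FALSE], 1, max)
    ct <- stats::cor.test(amp, covariate)
    data.frame(channel = ch, r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res
}
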