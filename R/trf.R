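# Temporal response function estimation by lagged regression.
#
# Conventions: the kernel w(f, l, c) maps feature f at lag l (ms, response
# following the stimulus for positive lags) to channel c;
# y(t, c) = sum_f sum_l x_f(t - l) w(f, l, c). Trials are modelled as
# independent; ridge fits centre each trial's design and response (so the
# intercept absorbs per-trial offsets), while the OLS impulse-train model is
# fit without centring to keep the kernel identical to the epoch-averaged
# evoked response when responses do not overlap.

#' Integer sample lags for a lag window
#'
#' @param lag_min_ms,lag_max_ms lag window in ms (defaults -100 to 800).
#' @param fs sample rate.
#' @return integer vector of lags in samples.
#' @export
lag_samples <- function(lag_min_ms = -100, lag_max_ms = 800, fs = 125) {
  lo <- as.integer(round(lag_min_ms / 1000 * fs))
  hi <- as.integer(round(lag_max_ms / 1000 * fs))
  if (hi < lo) stop("empty lag window")
  lo:hi
}

as_signal_matrix <- function(X) {
  if (is.list(X)) {
    nm <- names(X)
    X <- do.call(cbind, X)
    colnames(X) <- nm
  }
  as.matrix(X)
}

#' Lagged (time-expanded) design matrix
#'
#' Builds the TRF design: one column per (feature, lag), containing the
#' feature signal delayed by that lag, zero-padded at the trial boundaries.
#' Column order is feature-major, lag-minor and stable.
#'
#' @param X feature signals: an n x F matrix or a named list of length-n
#'   vectors.
#' @param lags integer lags in samples (see [lag_samples()]).
#' @return an n x (F * length(lags)) matrix with names `feature@lag`.
#' @export
lagged_design <- function(X, lags) {
  X <- as_signal_matrix(X)
  if (length(lags) == 0L) stop("empty lag window")
  n <- nrow(X); f <- ncol(X)
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(f))
  D <- matrix(0, n, f * length(lags))
  cn <- character(f * length(lags))
  col <- 0L
  for (j in seq_len(f)) {
    for (l in lags) {
      col <- col + 1L
      src <- seq_len(n) - l
      ok <- src >= 1L & src <= n
      D[ok, col] <- X[src[ok], j]
      cn[col] <- paste0(fn[j], "@", l)
    }
  }
  colnames(D) <- cn
  D
}

trial_grams <- function(trials, lags, center) {
  lapply(trials, function(tr) {
    D <- lagged_design(tr$X, lags)
    Y <- as.matrix(tr$Y)
    n <- nrow(D)
    if (center) {
      xm <- colMeans(D); ym <- colMeans(Y)
      D <- sweep(D, 2, xm); Y <- sweep(Y, 2, ym)
    }
    list(Sxx = crossprod(D), Sxy = crossprod(D, Y), n = n,
         yss = colSums(Y^2), names = colnames(D))
  })
}

new_trf_model <- function(W, intercept, feature_names, lags, fs, lambda,
                          model_tag = NA_character_) {
  L <- length(lags)
  # W is D x C with feature-major, lag-minor rows; reshape to F x L x C
  kern <- aperm(array(W, dim = c(L, length(feature_names), ncol(W))), c(2, 1, 3))
  dimnames(kern) <- list(feature_names, lags, colnames(W))
  structure(list(kernels = kern, intercept = intercept,
                 feature_names = feature_names,
                 lags = lags, lags_ms = lags / fs * 1000, fs = fs,
                 lambda = lambda, model_tag = model_tag),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d feature(s) x %d lag(s) x %d channel(s), lambda = %g\n",
              dim(x$kernels)[1], dim(x$kernels)[2], dim(x$kernels)[3], x$lambda))
  invisible(x)
}

solve_ridge <- function(Sxx, Sxy, n, lambda, standardize) {
  D <- nrow(Sxx)
  if (standardize) {
    s <- sqrt(diag(Sxx) / n)
    s[s == 0] <- 1
    Sxx <- Sxx / tcrossprod(s)
    Sxy <- Sxy / s
  } else s <- rep(1, D)
  A <- Sxx + diag(lambda, D)
  W <- tryCatch(solve(A, Sxy), error = function(e)
    stop("singular system; use lambda > 0", call. = FALSE))
  W / s
}

#' Fit a ridge-regularized TRF
#'
#' Closed-form ridge solution on the trials pooled (per-trial centred)
#' design: `W = (X'X + lambda I)^-1 X'Y`. Columns are z-scored with
#' pooled-trial statistics before penalization and the kernels are returned
#' on the original feature scale.
#'
#' @param trials list of trials, each `list(X = signals, Y = EEG)` where `X`
#'   is an n x F matrix or named list of signals and `Y` an n x C matrix.
#' @param lambda ridge parameter, >= 0.
#' @param lags integer lags in samples (default [lag_samples()] at `fs`).
#' @param fs sample rate (default 125).
#' @param standardize z-score design columns before penalizing (default
#'   `TRUE`).
#' @param model_tag optional label (`"A"`, `"AM"`, `"AMp"`, `"AMt"`, ...).
#' @return a `trf_model` with `kernels` of dim F x L x C.
#' @export
fit_ridge <- function(trials, lambda, lags = lag_samples(fs = fs), fs = 125,
                      standardize = TRUE, model_tag = NA_character_) {
  if (lambda < 0) stop("lambda must be >= 0")
  grams <- trial_grams(trials, lags, center = TRUE)
  Sxx <- Reduce(`+`, lapply(grams, `[[`, "Sxx"))
  Sxy <- Reduce(`+`, lapply(grams, `[[`, "Sxy"))
  n <- sum(vapply(grams, `[[`, 0L, "n"))
  W <- solve_ridge(Sxx, Sxy, n, lambda, standardize)
  fn <- feature_names_of(trials[[1]]$X)
  # intercept from the pooled means of the uncentred data
  xm <- Reduce(`+`, lapply(trials, function(tr)
    colMeans(lagged_design(tr$X, lags)) * nrow(as.matrix(tr$Y)))) / n
  ym <- Reduce(`+`, lapply(trials, function(tr)
    colMeans(as.matrix(tr$Y)) * nrow(as.matrix(tr$Y)))) / n
  new_trf_model(W, intercept = ym - drop(xm %*% W), feature_names = fn,
                lags = lags, fs = fs, lambda = lambda, model_tag = model_tag)
}

feature_names_of <- function(X) {
  if (is.list(X)) names(X)
  else if (!is.null(colnames(X))) colnames(X)
  else paste0("f", seq_len(ncol(as.matrix(X))))
}

#' Fit an impulse-train TRF by ordinary least squares
#'
#' The lambda = 0 solution on all trials pooled, without column scaling or
#' centring, preserving the interpretability of the kernel weights: with
#' isolated impulses the kernel equals the epoch-averaged evoked response.
#'
#' @inheritParams fit_ridge
#' @return a `trf_model`.
#' @export
fit_ols <- function(trials, lags = lag_samples(fs = fs), fs = 125,
                    model_tag = "downbeat") {
  grams <- trial_grams(trials, lags, center = FALSE)
  Sxx <- Reduce(`+`, lapply(grams, `[[`, "Sxx"))
  Sxy <- Reduce(`+`, lapply(grams, `[[`, "Sxy"))
  qrx <- qr(Sxx)
  if (qrx$rank < ncol(Sxx)) {
    bad <- grams[[1]]$names[qrx$pivot[(qrx$rank + 1L):ncol(Sxx)]]
    stop("rank-deficient design; collinear columns: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  W <- solve(Sxx, Sxy)
  new_trf_model(W, intercept = rep(0, ncol(W)),
                feature_names = feature_names_of(trials[[1]]$X),
                lags = lags, fs = fs, lambda = 0, model_tag = model_tag)
}

#' Predict EEG from a fitted TRF
#'
#' @param object a `trf_model`.
#' @param X feature signals (same names/order as at fit time).
#' @param ... unused.
#' @return predicted n x C matrix.
#' @export
predict.trf_model <- function(object, X, ...) {
  fn <- feature_names_of(X)
  if (!identical(fn, object$feature_names))
    stop("feature names do not match the fitted model")
  D <- lagged_design(X, object$lags)
  L <- length(object$lags)
  Fk <- dim(object$kernels)[1]; C <- dim(object$kernels)[3]
  W <- matrix(aperm(object$kernels, c(2, 1, 3)), nrow = Fk * L, ncol = C)
  sweep(D %*% W, 2, object$intercept, `+`)
}

# Per-channel Pearson r between held-out EEG and its prediction, computed
# entirely from Gram matrices: with centred-per-trial data,
#   <yhat, y> = colSums(W * Sxy_i),  |yhat|^2 = colSums(W * Sxx_i W),
#   |y|^2 stored at Gram time. Avoids rebuilding any design per fold.
loo_eval_multi <- function(Sxx_list, n_list, Sxy_lists, yss_lists,
                           lambda_grid, standardize) {
  n_tr <- length(Sxx_list)
  n_sub <- length(Sxy_lists)
  Sxx_tot <- Reduce(`+`, Sxx_list)
  n_tot <- sum(unlist(n_list))
  Sxy_tots <- lapply(Sxy_lists, function(l) Reduce(`+`, l))
  r_arr <- array(NA_real_, c(n_sub, n_tr, length(lambda_grid)))
  for (i in seq_len(n_tr)) {
    Sxx <- Sxx_tot - Sxx_list[[i]]
    n <- n_tot - n_list[[i]]
    if (standardize) {
      s <- sqrt(diag(Sxx) / n); s[s == 0] <- 1
    } else s <- rep(1, ncol(Sxx))
    ss <- tcrossprod(s)
    ev <- eigen(Sxx / ss, symmetric = TRUE)   # shared by all subjects
    Sxx_i <- Sxx_list[[i]] / ss
    for (sub in seq_len(n_sub)) {
      B <- crossprod(ev$vectors, (Sxy_tots[[sub]] - Sxy_lists[[sub]][[i]]) / s)
      Sxy_i <- Sxy_lists[[sub]][[i]] / s
      yss <- yss_lists[[sub]][[i]]
      for (k in seq_along(lambda_grid)) {
        W <- ev$vectors %*% (B / (ev$values + lambda_grid[k]))
        num <- colSums(W * Sxy_i)
        den2 <- colSums(W * (Sxx_i %*% W)) * yss
        r <- ifelse(den2 > 0, num / sqrt(den2), NA)
        if (anyNA(r)) {
          warning("constant channel: r set to 0")
          r[is.na(r)] <- 0
        }
        r_arr[sub, i, k] <- mean(r)
      }
    }
  }
  r_arr
}

loo_eval_grams <- function(grams, lambda_grid, standardize) {
  r <- loo_eval_multi(lapply(grams, `[[`, "Sxx"),
                      lapply(grams, `[[`, "n"),
                      list(lapply(grams, `[[`, "Sxy")),
                      list(lapply(grams, `[[`, "yss")),
                      lambda_grid, standardize)
  matrix(r[1, , ], length(grams), length(lambda_grid))
}

#' Leave-one-out cross-validated TRF evaluation
#'
#' For every lambda on the grid, fits on N-1 trials and predicts the
#' held-out trial; prediction accuracy is the Pearson correlation between
#' predicted and recorded EEG per channel, averaged over channels. The
#' lambda maximizing the mean accuracy over trials is selected and the
#' per-trial accuracies at that lambda reported.
#'
#' @inheritParams fit_ridge
#' @param lambda_grid candidate ridge parameters (default `10^(-3:3)`).
#' @return object of class `fit_report`: list with `r_per_trial`,
#'   `best_lambda`, `mean_r_by_lambda`, `lambda_grid`, `model_tag`.
#' @export
loo_crossval <- function(trials, lambda_grid = 10^(-3:3),
                         lags = lag_samples(fs = fs), fs = 125,
                         standardize = TRUE, model_tag = NA_character_) {
  if (length(trials) < 3L) stop("leave-one-out needs at least 3 trials")
  grams <- trial_grams(trials, lags, center = TRUE)
  r_mat <- loo_eval_grams(grams, lambda_grid, standardize)
  mean_r <- colMeans(r_mat)
  best <- which.max(mean_r)
  structure(list(r_per_trial = r_mat[, best],
                 best_lambda = lambda_grid[best],
                 mean_r_by_lambda = mean_r,
                 lambda_grid = lambda_grid,
                 model_tag = model_tag),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s: mean r = %.4f (best lambda = %g, %d trials)\n",
              x$model_tag, mean(x$r_per_trial), x$best_lambda,
              length(x$r_per_trial)))
  invisible(x)
}
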