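sim_xy <- function(n, features, kernel_list, lags, noise_sd = 0, n_chan = 2,
                   seed = 1) {
  # direct forward model independent of the package's simulator
  set.seed(seed)
  X <- lapply(features, function(f) {
    x <- numeric(n); x[sample.int(n - max(abs(lags)) - 1, 15) + max(abs(lags))] <- 1
    x
  })
  names(X) <- features
  Y <- matrix(0, n, n_chan)
  for (c in seq_len(n_chan)) {
    for (f in features) {
      k <- kernel_list[[f]][, c]
      for (j in seq_along(lags)) {
        l <- lags[j]
        src <- seq_len(n) - l
        ok <- src >= 1 & src <= n
        Y[ok, c] <- Y[ok, c] + k[j] * X[[f]][src[ok]]
      }
    }
  }
  Y <- Y + matrix(rnorm(n * n_chan, sd = noise_sd), n, n_chan)
  list(X = X, Y = Y)
}

test_that("lagged_design implements the convolution expansion", {
  x <- c(0, 0, 1, 0, 0)
  D <- lagged_design(list(a = x), lags = 0L)
  expect_equal(drop(D), x)

  D2 <- lagged_design(list(a = x), lags = 0:2)
  expect_equal(D2[, 1], x)
  expect_equal(D2[, 2], c(0, 0, 0, 1, 0))   # shifted identity structure
  expect_equal(D2[, 3], c(0, 0, 0, 0, 1))

  D3 <- lagged_design(list(a = x, b = rev(x)), lags = -1:1)
  expect_identical(ncol(D3), 6L)
  expect_identical(colnames(D3)[1:3], c("a@-1", "a@0", "a@1"))
  expect_error(lagged_design(list(a = x), integer(0)), "empty lag")
})

test_that("ridge shrinks monotonically and recovers noiseless kernels", {
  lags <- 0:10
  k <- list(a = matrix(sin(seq(0, pi, length.out = 11)), ncol = 2, nrow = 11),
            b = matrix(cos(seq(0, pi, length.out = 11)), ncol = 2, nrow = 11))
  d <- sim_xy(600, c("a", "b"), k, lags, noise_sd = 0)
  trials <- list(list(X = d$X, Y = d$Y))

  fit <- fit_ridge(trials, lambda = 1e-6, lags = lags, fs = 100)
  expect_lt(max(abs(fit$kernels[1, , 1] - k$a[, 1])) / max(abs(k$a)), 1e-6)
  expect_lt(max(abs(fit$kernels[2, , 2] - k$b[, 2])) / max(abs(k$b)), 1e-6)

  norms <- vapply(c(1e-2, 1, 1e2, 1e4), function(l)
    sum(fit_ridge(trials, l, lags = lags, fs = 100)$kernels^2), 0)
  expect_true(all(diff(norms) < 0))

  # duplicating a trial leaves the solution unchanged
  fit2 <- fit_ridge(c(trials, trials), lambda = 1e-6, lags = lags, fs = 100)
  expect_equal(fit2$kernels, fit$kernels, tolerance = 1e-8)
})

test_that("predict is linear and reproduces noiseless training data", {
  lags <- 0:8
  k <- list(a = matrix(rnorm(9 * 2), 9, 2))
  d <- sim_xy(400, "a", k, lags, noise_sd = 0, seed = 2)
  fit <- fit_ridge(list(list(X = d$X, Y = d$Y)), 1e-8, lags = lags, fs = 100)
  pred <- predict(fit, d$X)
  expect_equal(pred, d$Y, tolerance = 1e-5, ignore_attr = TRUE)

  scaled <- predict(fit, list(a = 2 * d$X$a))
  expect_equal(sweep(scaled, 2, fit$intercept),
               2 * sweep(pred, 2, fit$intercept), tolerance = 1e-8)

  expect_error(predict(fit, list(b = d$X$a)), "feature names")
})

test_that("OLS equals epoch-averaged evoked responses for isolated impulses", {
  fs <- 100; lags <- 0:30
  onsets <- seq(0.5, 15, by = 1.0)       # 1 s apart > 0.3 s lag span
  m <- note_sequence(onsets, rep(0.2, length(onsets)), rep(60, length(onsets)))
  x <- impulse_train(m, fs = fs, duration_s = 16)
  set.seed(4)
  Y <- matrix(rnorm(length(x) * 3), ncol = 3)
  fit <- fit_ols(list(list(X = list(onset = x), Y = Y)), lags = lags, fs = fs)
  idx <- which(x != 0)
  for (ch in 1:3) {
    erp <- vapply(lags, function(l) mean(Y[idx + l, ch]), 0)
    expect_lt(max(abs(fit$kernels[1, , ch] - erp)), 1e-8)
  }
})

test_that("OLS attributes zero kernels to redundant regressors", {
  fs <- 100; lags <- 0:20
  set.seed(5)
  x <- numeric(2000); x[sample(100:1900, 40)] <- 1
  db <- x; db[db == 1] <- rbinom(sum(x), 1, 0.4)
  k_on <- sin(seq(0, pi, length.out = 21))
  y <- numeric(2000)
  for (j in seq_along(lags)) {
    src <- seq_len(2000) - lags[j]; ok <- src >= 1
    y[ok] <- y[ok] + k_on[j] * x[src[ok]]
  }
  y <- y + rnorm(2000, sd = 0.01)
  fit <- fit_ols(list(list(X = list(onset = x, DBo = db), Y = cbind(y))),
                 lags = lags, fs = fs)
  expect_lt(max(abs(fit$kernels["DBo", , 1])), 0.05)
  expect_gt(cor(fit$kernels["onset", , 1], k_on), 0.999)

  # rank deficiency is reported with the collinear columns
  expect_error(
    fit_ols(list(list(X = list(a = x, b = x), Y = cbind(y))), lags = lags, fs = fs),
    "collinear")
})

test_that("leave-one-out selection behaves at the grid ends and under noise", {
  lags <- 0:10
  k <- list(a = matrix(rnorm(11 * 2), 11, 2))
  trials <- lapply(1:4, function(i)
    sim_xy(500, "a", k, lags, noise_sd = 1e-3, seed = i))
  trials <- lapply(trials, function(d) list(X = d$X, Y = d$Y))

  rep <- loo_crossval(trials, lambda_grid = 10^(-3:3), lags = lags, fs = 100)
  expect_s3_class(rep, "fit_report")
  expect_gte(mean(rep$r_per_trial), 0.9)
  expect_lte(rep$best_lambda, 1)          # high SNR favours light shrinkage
  expect_true(all(is.finite(rep$mean_r_by_lambda)))

  # grid of one returns it
  one <- loo_crossval(trials, lambda_grid = 1, lags = lags, fs = 100)
  expect_identical(one$best_lambda, 1)

  # pure noise: r near zero
  null_trials <- lapply(1:4, function(i) {
    set.seed(100 + i)
    list(X = list(a = rnorm(500)), Y = matrix(rnorm(1000), ncol = 2))
  })
  nrep <- loo_crossval(null_trials, lambda_grid = 10^(-1:2), lags = lags, fs = 100)
  expect_lt(abs(mean(nrep$r_per_trial)), 2 / sqrt(500))

  expect_error(loo_crossval(trials[1:2], 1, lags = lags, fs = 100), "3 trials")
})
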