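test_that("delta_r_table contrasts each expectation model against A", {
  rep <- expand.grid(participant = 1:2, stimset = 1:2,
                     stim_category = c("original", "chimeric"),
                     model_tag = c("A", "AM", "AMp"),
                     stringsAsFactors = FALSE)
  rep$r <- 0.09 + 0.01 * (rep$model_tag != "A")
  tab <- delta_r_table(rep)
  expect_identical(nrow(tab), 16L)   # 2 participants x 2 sets x 2 cats x 2 contrasts
  expect_setequal(unique(tab$contrast), c("AM-A", "AMp-A"))
  expect_equal(tab$delta_r, rep(0.01, 16))

  same <- rep; same$r <- 0.1
  expect_true(all(delta_r_table(same)$delta_r == 0))

  expect_error(delta_r_table(rep[rep$model_tag != "A", ]), "unmatched")
})

test_that("Holm adjustment matches the hand-applied step-down rule", {
  # paired data constructed so the raw p-values are known through t.test
  set.seed(8)
  mk_pair <- function(shift) {
    x <- rnorm(12)
    list(x + shift + rnorm(12, sd = 0.5), x)
  }
  comps <- list(c1 = mk_pair(0.8), c2 = mk_pair(0.1), c3 = mk_pair(0.4))
  res <- paired_tests_holm(comps)
  raw <- vapply(comps, function(xy) t.test(xy[[1]], xy[[2]], paired = TRUE)$p.value, 0)
  expect_equal(res$p_raw, unname(raw), tolerance = 1e-12)
  expect_equal(res$p_holm, oracle_holm(res$p_raw), tolerance = 1e-12)
  expect_true(all(res$p_holm >= res$p_raw))
  expect_true(!is.unsorted(res$p_holm[order(res$p_raw)]))

  # identical vectors: t = 0, p = 1
  v <- rnorm(10)
  same <- paired_tests_holm(list(id = list(v, v)))
  expect_identical(same$t, 0)
  expect_identical(same$p_raw, 1)

  # single comparison: Holm equals raw
  single <- paired_tests_holm(comps[1])
  expect_equal(single$p_holm, single$p_raw)
})

test_that("TFCE matches the Riemann-sum closed form for an isolated point", {
  tm <- matrix(0, 4, 5); tm[2, 3] <- 2
  dh <- 2 / 50
  sc <- tfce(tm, E = 0.5, H = 2, dh = dh)
  hs <- seq(dh, 2, by = dh)
  expect_equal(sc[2, 3], sum(hs^2 * dh), tolerance = 1e-12)
  expect_true(all(sc[tm == 0] == 0))

  # all-zero map
  expect_true(all(tfce(matrix(0, 3, 3)) == 0))

  # negative values are enhanced on their own sign
  expect_equal(tfce(-tm, E = 0.5, H = 2, dh = dh)[2, 3], -sum(hs^2 * dh),
               tolerance = 1e-12)
})

test_that("TFCE extent doubling scales plateau scores by 2^E", {
  h0 <- 3; dh <- h0 / 50
  base <- matrix(0, 2, 12); base[1, 3:4] <- h0
  wide <- matrix(0, 2, 12); wide[1, 3:6] <- h0
  s1 <- tfce(base, E = 0.5, H = 2, dh = dh)[1, 3]
  s2 <- tfce(wide, E = 0.5, H = 2, dh = dh)[1, 3]
  expect_equal(s2 / s1, 2^0.5, tolerance = 1e-12)

  # scaling the map preserves score order
  set.seed(9)
  tm <- matrix(rnorm(40), 4, 10)
  a <- tfce(tm); b <- tfce(3 * tm)
  expect_identical(order(a), order(b))
})

test_that("sign-flip permutation p-values are valid and sign-symmetric", {
  set.seed(10)
  X <- array(rnorm(6 * 4 * 10), c(6, 4, 10))
  adj <- cbind(1:3, 2:4)
  res <- signflip_permutation(X, adj, n_perm = 199, seed = 3)
  expect_true(all(res$p_map > 0 & res$p_map <= 1))
  expect_gte(min(res$p_map), 1 / 200)

  flipped <- signflip_permutation(-X, adj, n_perm = 199, seed = 3)
  expect_equal(flipped$p_map, res$p_map, tolerance = 1e-12)
  expect_equal(abs(flipped$t_map), abs(res$t_map), tolerance = 1e-12)

  expect_warning(signflip_permutation(X, adj, n_perm = 50, seed = 1), "coarse")
})

test_that("a strong planted effect is detected where it was planted", {
  set.seed(12)
  X <- array(rnorm(8 * 6 * 20, sd = 0.3), c(8, 6, 20))
  X[, 2:3, 8:11] <- X[, 2:3, 8:11] + 2       # frontocentral-like cluster
  adj <- cbind(1:5, 2:6)
  res <- signflip_permutation(X, adj, n_perm = 499, seed = 4)
  sig <- res$p_map < 0.05
  expect_true(all(sig[2:3, 8:11]))
  expect_lt(mean(sig[, c(1:5, 16:20)]), 0.2)  # mostly quiet off the effect
})

test_that("peak correlations with a covariate are FDR-controlled per channel", {
  set.seed(13)
  ns <- 16; nc <- 5; nl <- 30
  lags_ms <- seq(0, 580, by = 20)
  covar <- runif(ns, 0, 11)
  kern <- array(rnorm(ns * nc * nl, sd = 0.05), c(ns, nc, nl))
  bump <- exp(-0.5 * ((lags_ms - 200) / 40)^2)
  for (s in 1:ns) kern[s, 1:2, ] <- kern[s, 1:2, ] +
    rep(bump, each = 2) * (0.2 + 0.1 * covar[s])
  res <- peak_correlation_fdr(kern, lags_ms, c(100, 300), covar)
  expect_equal(res$p_fdr, oracle_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$p_fdr[1:2] < 0.05))
  expect_true(all(res$r[1:2] > 0))

  one <- peak_correlation_fdr(kern[, 1, , drop = FALSE], lags_ms, c(100, 300), covar)
  expect_equal(one$p_fdr, one$p)

  expect_error(peak_correlation_fdr(kern, lags_ms, c(100, 300), rep(1, ns)),
               "constant covariate")
})

test_that("the shipped montage is a symmetric 32-channel neighbour graph", {
  mon <- montage_adjacency()
  expect_length(mon$channels, 32L)
  expect_true(all(c("Fz", "Cz", "TP9", "PO10") %in% mon$channels))
  expect_true(all(mon$edges >= 1 & mon$edges <= 32))
  expect_false(any(mon$edges[, 1] == mon$edges[, 2]))
})
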