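test_that("Pearson screen matches hand-computed values and Bonferroni rule", {
  out <- pearson_family(list(a = c(1, 2, 3, 4, 5)), c(2, 1, 4, 3, 5))
  expect_equal(out$r, 0.8)

  ident <- pearson_family(list(a = 1:10 + 0), 1:10 + 0)
  expect_equal(ident$r, 1)
  expect_lt(ident$p, 1e-12)

  set.seed(1)
  four <- pearson_family(
    list(w = rnorm(20), x = rnorm(20), y = rnorm(20), z = rnorm(20)),
    rnorm(20))
  expect_equal(nrow(four), 4L)
  expect_equal(unique(four$alpha_adjusted), 0.0125)

  expect_error(pearson_family(list(flat = rep(1, 10)), rnorm(10)), "flat")
})

test_that("skipped correlation equals plain Pearson when nothing is flagged", {
  set.seed(2)
  found <- 0L
  for (s in 1:20) {
    x <- rnorm(15)
    y <- 0.9 * x + rnorm(15) * 0.2
    if (length(skipped_outliers(x, y)) == 0L) {
      found <- found + 1L
      sk <- skipped_pearson(x, y, n_boot = 0)
      expect_identical(sk$r, cor(x, y))
    }
  }
  expect_gte(found, 3L)  # clean datasets with empty flag sets do occur

  # collinear data: r exactly 1, no outliers
  x <- seq_len(12) + 0
  sk <- skipped_pearson(x, 2 * x + 1, n_boot = 0)
  expect_equal(sk$r, 1)
  expect_length(sk$outlier_indices, 0L)
})

test_that("the projection rule matches a plain-loop oracle", {
  set.seed(3)
  for (rep in 1:8) {
    n <- 25
    x <- rnorm(n)
    y <- 0.6 * x + rnorm(n) * 0.8
    if (rep %% 2 == 0) {  # plant a gross opposing outlier
      x[n] <- 6
      y[n] <- -6
    }
    expect_identical(skipped_outliers(x, y), oracle_skipped_outliers(x, y))
  }
})

test_that("a planted gross outlier is flagged and neutralized", {
  set.seed(4)
  n <- 26
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n) * 0.8
  r_clean <- cor(x, y)
  # a point 10 SDs out, opposing the trend
  xx <- c(x, 10)
  yy <- c(y, -10)
  sk <- skipped_pearson(xx, yy, n_boot = 0)
  expect_true(27L %in% sk$outlier_indices)
  expect_lte(abs(sk$r - r_clean), 0.1)
  # the raw Pearson, by contrast, is wrecked
  expect_gt(abs(cor(xx, yy) - r_clean), 0.3)
})

test_that("bootstrap inference is seeded, sized and ordered correctly", {
  set.seed(5)
  x <- rnorm(20)
  y <- 0.8 * x + rnorm(20) * 0.4
  a <- skipped_pearson(x, y, n_boot = 150, seed = 9)
  b <- skipped_pearson(x, y, n_boot = 150, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_identical(a$p, b$p)
  expect_lte(a$ci[1], a$ci[2])
  expect_equal(a$n_boot, 150L)
  expect_lte(a$p, 1)
})

test_that("bootstrap CI usually covers the full-sample skipped r", {
  set.seed(6)
  cover <- vapply(1:10, function(k) {
    x <- rnorm(18)
    y <- 0.6 * x + rnorm(18) * 0.8
    sk <- skipped_pearson(x, y, n_boot = 150, seed = 100 + k)
    sk$ci[1] <= sk$r && sk$r <= sk$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("LOO-CV predictions equal explicit per-fold refits", {
  # noiseless line: predictions reproduce the outcome exactly
  x <- c(0, 1, 2, 3)
  y <- 2 * x + 1
  out <- loocv_predict(x, y)
  expect_equal(out$predictions, y)
  expect_equal(out$r_pred_obs, 1)

  # hand-enumerated folds for x = 0:3, y = (0, 1, 2, 10)
  out2 <- loocv_predict(c(0, 1, 2, 3), c(0, 1, 2, 10))
  expect_equal(out2$predictions, c(-14 / 3, 2, 6, 3))
  expect_equal(out2$r_pred_obs,
               cor(c(-14 / 3, 2, 6, 3), c(0, 1, 2, 10)))

  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(15)
    y <- 0.5 * x + rnorm(15)
    expect_equal(loocv_predict(x, y)$predictions, oracle_loocv(x, y))
  }

  expect_error(loocv_predict(c(1, 1, 1, 2), c(1, 2, 3, 4)), "fold 4")
})

test_that("cross-validated correlation is negative under independence", {
  set.seed(8)
  r_null <- vapply(1:40, function(k) {
    loocv_predict(rnorm(50), rnorm(50))$r_pred_obs
  }, numeric(1))
  expect_lt(mean(r_null), 0)
})

test_that("permutation p is deterministic, two-sided and floored at 2/(n+1)", {
  x <- 0:9 + 0
  y <- 2 * x + 1
  out <- loocv_permutation_test(x, y, n_perm = 999, seed = 1)
  expect_equal(out$p_perm, 2 / 1000)

  set.seed(9)
  xr <- rnorm(20)
  yr <- 0.5 * xr + rnorm(20)
  a <- loocv_permutation_test(xr, yr, n_perm = 400, seed = 3)
  b <- loocv_permutation_test(xr, yr, n_perm = 400, seed = 3)
  expect_identical(a$p_perm, b$p_perm)
  expect_gt(a$p_perm, 0)
  expect_lte(a$p_perm, 1)
})

test_that("permutation p under the null is near-uniform", {
  set.seed(10)
  p <- vapply(1:60, function(k) {
    loocv_permutation_test(rnorm(27), rnorm(27), n_perm = 300,
                           seed = 5000 + k)$p_perm
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0)
  expect_lte(mean(p < 0.05), 0.15)
  expect_lt(max(abs(sort(p) - seq_along(p) / length(p))), 0.25)
})
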