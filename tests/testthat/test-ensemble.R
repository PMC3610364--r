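test_that("bagging draws deterministic full-size two-class resamples", {
  bl <- blob_data(12, seed = 61)
  mods <- bagging_train(bl$x, bl$y, k = 5, seed = 9)
  expect_length(mods, 5)
  idx <- lapply(mods, attr, "indices")
  expect_true(all(vapply(idx, length, integer(1)) == 24))
  again <- bagging_train(bl$x, bl$y, k = 5, seed = 9)
  expect_identical(idx, lapply(again, attr, "indices"))
  for (i in idx) expect_equal(length(unique(bl$y[i])), 2)
})

test_that("bootstrap resamples contain about 1 - 1/e unique samples", {
  bl <- blob_data(50, seed = 62)
  mods <- bagging_train(bl$x, bl$y, k = 200, seed = 3)
  frac <- vapply(mods, function(m)
    length(unique(attr(m, "indices"))) / 100, numeric(1))
  expect_equal(mean(frac), 1 - exp(-1), tolerance = 0.01)
})

test_that("bagging output is the arithmetic mean of component outputs", {
  bl <- blob_data(8, seed = 63)
  mods <- bagging_train(bl$x, bl$y, k = 5, seed = 4)
  g <- vapply(mods, decision_value, numeric(nrow(bl$x)), x = bl$x)
  expect_equal(bagging_predict(mods, bl$x), rowMeans(g), tolerance = 1e-12)
  # identical components collapse to the component output
  same <- rep(mods[1], 3)
  expect_equal(bagging_predict(same, bl$x), g[, 1], tolerance = 1e-12)
  expect_error(bagging_predict(list(), bl$x), "empty")
})

test_that("fusion weights match the closed form and its limits", {
  expect_equal(dwf_weights(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(dwf_weights(c(1, 2)), c(2 / 3, 1 / 3))
  expect_equal(dwf_weights(c(0, 1, 1)), c(1, 0, 0))
  expect_equal(dwf_weights(c(0, 1, 0)), c(0.5, 0, 0.5))
  expect_error(dwf_weights(numeric(0)), "no component")
})

test_that("double-sum weights equal the simplified inverse-error form", {
  set.seed(64)
  for (rep in 1:200) {
    e <- runif(5, 0.1, 2)
    w <- dwf_weights(e)
    expect_equal(w, (1 / e) / sum(1 / e), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-10)
    expect_true(all(w >= 0))
  }
})

test_that("signed-error mode reproduces the literal formula", {
  cfg <- ensemble_config(error_transform = "signed")
  e <- c(1, -2, 0.5)
  inv <- 1 / e
  expect_equal(dwf_weights(e, cfg), inv * sum(inv) / sum(outer(inv, inv)))
})

test_that("ensemble error follows the printed closed form", {
  expect_equal(dwf_ensemble_error(c(1, 2)), 4 / 9)
  for (k in c(2, 5, 9)) {
    expect_equal(dwf_ensemble_error(rep(1, k)), 1 / k^2)
  }
  z <- dwf_ensemble_error(c(0, 1))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "zero_error"))
  # the weighted double sum differs from the closed form by K^2
  set.seed(65)
  e <- runif(5, 0.2, 1.5)
  w <- dwf_weights(e)
  expect_equal(dwf_weighted_squared_error(e, w),
               25 * dwf_ensemble_error(e), tolerance = 1e-12)
})

test_that("every component error dominates the ensemble error", {
  set.seed(66)
  for (rep in 1:200) {
    e <- runif(5, 0.05, 3)
    e2 <- dwf_ensemble_error(e)
    expect_gte(min(e^2) / e2, 1)
    expect_lte(e2, min(e^2))
  }
})

test_that("dwf_predict fuses component outputs with per-sample weights", {
  bl <- blob_data(10, seed = 67)
  mods <- bagging_train(bl$x, bl$y, k = 5, seed = 5)
  fr <- dwf_predict(mods, bl$x, labels = bl$y)
  expect_s3_class(fr, "fusion_result")
  expect_equal(dim(fr$g), c(20, 5))
  expect_equal(rowSums(fr$w), rep(1, 20), tolerance = 1e-10)
  expect_true(all(fr$w >= 0))
  expect_equal(fr$per_sample$g_dwf, rowSums(fr$w * fr$g),
               tolerance = 1e-12)
  expect_equal(fr$e, matrix(bl$y, 20, 5) - fr$g, tolerance = 1e-12)
  # a single component passes through unchanged
  fr1 <- dwf_predict(mods[1], bl$x, labels = bl$y)
  expect_equal(fr1$per_sample$g_dwf, fr$g[, 1], tolerance = 1e-12)
  expect_error(dwf_predict(mods, bl$x), "labels")
})

test_that("estimated mode uses constant per-component error estimates", {
  bl <- blob_data(10, seed = 68)
  mods <- bagging_train(bl$x, bl$y, k = 3, seed = 6)
  cfg <- ensemble_config(k = 3, dwf_mode = "estimated")
  est <- c(0.5, 1, 2)
  fr <- dwf_predict(mods, bl$x, error_estimates = est, config = cfg)
  w <- dwf_weights(est)
  expect_equal(fr$w, matrix(w, 20, 3, byrow = TRUE), tolerance = 1e-12)
  expect_error(dwf_predict(mods, bl$x, error_estimates = c(1, 2),
                           config = cfg), "one error estimate per model")
})

test_that("fusion reports round trip through CSV", {
  dir <- withr::local_tempdir()
  bl <- blob_data(6, seed = 69)
  mods <- bagging_train(bl$x, bl$y, k = 2, seed = 7)
  fr <- dwf_predict(mods, bl$x, labels = bl$y,
                    config = ensemble_config(k = 2))
  fp <- file.path(dir, "fusion.csv")
  write_fusion_report(fr, ids = paste0("s", 1:12), labels = bl$y, fp)
  back <- utils::read.csv(fp)
  expect_named(back, c("id", "label", "g_1", "g_2", "e_1", "e_2",
                       "w_1", "w_2", "g_dwf", "e2_dwf"))
  expect_equal(back$g_dwf, fr$per_sample$g_dwf, tolerance = 1e-10)
})
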