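test_that("the low-pass prefilter has unit DC gain and the designed rolloff", {
  fs <- 2000
  dc <- butterworth_lowpass(rep(1, 3000), fs, delay_samples = 0)
  expect_equal(dc[2500], 1, tolerance = 1e-6)
  g50 <- measured_gain(function(x)
    butterworth_lowpass(x, fs, delay_samples = 0), 50, fs)
  expect_equal(g50, 1 / sqrt(2), tolerance = 1e-6)
  g200 <- measured_gain(function(x)
    butterworth_lowpass(x, fs, delay_samples = 0), 200, fs)
  expect_lt(20 * log10(g200), -60)
  expect_error(butterworth_lowpass(rnorm(100), fs = 80, fc = 50), "Nyquist")
})

test_that("delay compensation advances the output and zero-pads the tail", {
  fs <- 2000
  x <- sin(2 * pi * 5 * (0:1999) / fs)
  y0 <- butterworth_lowpass(x, fs, delay_samples = 0)
  y <- butterworth_lowpass(x, fs, delay_samples = 100)
  expect_equal(y[1:1900], y0[101:2000])
  expect_identical(y[1901:2000], numeric(100))
})

test_that("turns count matches hand-enumerated examples", {
  expect_equal(count_turns_fixed_threshold(c(0, 0.5, 0.1, 0.6, 0.55)), 3)
  expect_equal(count_turns_fixed_threshold(c(0, 0.15, 0.05, 0.25, 0.1)), 0)
  expect_equal(count_turns_fixed_threshold(seq(0, 1, 0.1)), 0)
  expect_error(count_turns_fixed_threshold(c(0, 1)), "3 samples")
  # threshold is strict: a step of exactly 0.2 does not count
  expect_equal(count_turns_fixed_threshold(c(0, 0.2, 0.1, 0.25, 0.2),
                                           threshold = 0.2), 0)
})

test_that("turns count is invariant to constant offsets", {
  set.seed(41)
  x <- cumsum(rnorm(200, sd = 0.3))
  tc <- count_turns_fixed_threshold(x)
  expect_equal(count_turns_fixed_threshold(x + 5), tc)
  # the amplitude condition reads the difference from the *preceding*
  # sample, so reversal can move a turn across the threshold; with a zero
  # threshold every direction change counts and reversal is exact
  expect_equal(count_turns_fixed_threshold(rev(x), threshold = 0),
               count_turns_fixed_threshold(x, threshold = 0))
})

test_that("form factor behaves like a complexity/mobility ratio", {
  fs <- 4000
  t <- (0:3999) / fs
  expect_equal(form_factor(sin(2 * pi * 10 * t)), 1, tolerance = 1e-3)
  two_tone <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 100 * t)
  expect_gt(form_factor(two_tone), 1)
  expect_error(form_factor(rep(1, 100)), "zero-variance")
  # scale invariance
  set.seed(42)
  x <- rnorm(300)
  expect_equal(form_factor(3.7 * x), form_factor(x), tolerance = 1e-12)
  expect_equal(form_factor(-x), form_factor(x), tolerance = 1e-12)
  ff <- ff_halves(c(sin(2 * pi * 10 * t), two_tone))
  expect_named(ff, c("ff1", "ff2"))
  expect_gt(ff["ff2"], ff["ff1"])
})

test_that("variance of segment mean squares matches hand computation", {
  expect_equal(variance_of_mean_squared(c(1, 1, 2, 2), 2), 4.5)
  expect_equal(variance_of_mean_squared(rep(c(1, 2), 10), 2), 0)
  expect_error(variance_of_mean_squared(1:10, 10), "2 full segments")
  expect_error(variance_of_mean_squared(1:10, 11), "exceeds")
  # quartic scaling under amplitude scaling
  set.seed(43)
  x <- rnorm(400)
  expect_equal(variance_of_mean_squared(2 * x, 50),
               16 * variance_of_mean_squared(x, 50), tolerance = 1e-9)
})

test_that("Parzen density mean equals the sample mean via quadrature", {
  expect_equal(parzen_pdf_mean(0.3, bandwidth = 0.05), 0.3,
               tolerance = 1e-9)
  sym <- c(0.2, 0.8, 0.4, 0.6, 0.5)
  expect_equal(parzen_pdf_mean(sym, bandwidth = 0.1), 0.5,
               tolerance = 1e-9)
  set.seed(44)
  x <- runif(300)
  expect_equal(parzen_pdf_mean(x), mean(x), tolerance = 1e-6)
  expect_error(parzen_pdf_mean(x, bandwidth = 0), "bandwidth")
})

test_that("spectral fractal dimension recovers power-law exponents", {
  fs <- 2000
  cases <- list(list(beta = 2, fd = 1.5, tol = 0.1),
                list(beta = 3, fd = 1.0, tol = 0.1),
                list(beta = 0, fd = 2.5, tol = 0.15))
  for (cs in cases) {
    set.seed(100 + cs$beta)
    x <- synth_power_law_noise(4096, cs$beta, fs)
    expect_equal(fractal_dimension_psd(x, fs, fit_band = c(10, 500)),
                 cs$fd, tolerance = cs$tol)
  }
  expect_error(fractal_dimension_psd(rnorm(512), fs, c(10, 1200)),
               "fit_band")
  expect_error(fractal_dimension_psd(rnorm(32), fs), "64 samples")
})

test_that("feature vectors are deterministic with the documented layout", {
  s <- generate_synthetic_cohort(
    test_cohort_params(seed = 8, n_normal = 1, n_abnormal = 1))[[2]]
  v1 <- extract_feature_vector(s)
  v2 <- extract_feature_vector(s)
  expect_identical(v1, v2)
  expect_named(v1, c("natom", "tcft", "ff1", "ff2", "vms", "mu", "fd"))
  expect_true(all(is.finite(v1)))
  expect_gte(v1["natom"], 0)
  expect_gte(v1["tcft"], 0)
})

test_that("pooled t-test matches hand computation and conventions", {
  r <- two_sample_t_test(c(0, 1), c(2, 3))
  expect_equal(abs(r$t), 2.828, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.1056, tolerance = 1e-3)
  sw <- two_sample_t_test(c(2, 3), c(0, 1))
  expect_equal(sw$t, -r$t)
  expect_equal(sw$p, r$p)
  same <- two_sample_t_test(c(1, 1, 1), c(1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(two_sample_t_test(c(1, 1), c(2, 2))$p, 0)
  expect_error(two_sample_t_test(1, c(1, 2)), "at least 2")
})
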