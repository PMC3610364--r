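test_that("amplitude normalization maps linearly onto [0, 1]", {
  expect_equal(normalize_amplitude(c(-1, 0, 1)), c(0, 0.5, 1))
  already <- c(0, 0.25, 1)
  expect_equal(normalize_amplitude(already), already)
  # ordering of samples is preserved
  set.seed(11)
  x <- rnorm(50)
  expect_identical(order(normalize_amplitude(x)), order(x))
})

test_that("normalization is idempotent and rejects constant signals", {
  set.seed(2)
  x <- cumsum(rnorm(100))
  expect_equal(normalize_amplitude(normalize_amplitude(x)),
               normalize_amplitude(x))
  expect_error(normalize_amplitude(c(3, 3, 3)), "constant")
})

test_that("vag_signal validates its invariants", {
  expect_error(vag_signal(c(1, NA, 2)), "finite")
  expect_error(vag_signal(1), "2 samples")
  expect_error(vag_signal(c(1, 2), fs = 0), "fs")
  s <- vag_signal(c(1, 2, 3), fs = 256, label = "abnormal", id = "x")
  expect_s3_class(s, "vag_signal")
  expect_identical(encode_labels(c("abnormal", "normal")), c(1, -1))
  expect_error(encode_labels("bad"), "label")
})

test_that("synthetic cohorts honor counts, length and determinism", {
  p <- test_cohort_params(seed = 5, n_normal = 3, n_abnormal = 2)
  cohort <- generate_synthetic_cohort(p)
  expect_length(cohort, 5)
  expect_true(all(vapply(cohort, function(s) length(s$samples),
                         numeric(1)) == 1024))
  expect_identical(vapply(cohort, function(s) s$label, character(1)),
                   c(rep("normal", 3), rep("abnormal", 2)))
  again <- generate_synthetic_cohort(p)
  expect_identical(cohort, again)
  empty <- generate_synthetic_cohort(
    test_cohort_params(n_normal = 0, n_abnormal = 0))
  expect_length(empty, 0)
  expect_error(cohort_params(n_normal = -1), ">= 0")
})

test_that("abnormal signals have larger per-signal spread across seeds", {
  hits <- 0L
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    cohort <- generate_synthetic_cohort(test_cohort_params(seed = seed))
    sds <- vapply(cohort, function(s) sd(s$samples), numeric(1))
    lab <- vapply(cohort, function(s) s$label, character(1))
    if (mean(sds[lab == "abnormal"]) > mean(sds[lab == "normal"]))
      hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("quantization stays on a grid of the requested resolution", {
  p <- test_cohort_params(seed = 3, n_normal = 1, n_abnormal = 1)
  p$quantization_bits <- 12
  s <- generate_synthetic_cohort(p)[[1]]$samples
  rng <- range(s)
  q <- (s - rng[1]) / (rng[2] - rng[1]) * (2^12 - 1)
  expect_equal(q, round(q), tolerance = 1e-9)
})

test_that("manifest round trip reproduces the cohort", {
  dir <- withr::local_tempdir()
  cohort <- generate_synthetic_cohort(
    test_cohort_params(seed = 9, n_normal = 2, n_abnormal = 1))
  mp <- write_cohort(cohort, dir)
  back <- read_manifest(mp, fs = 256)
  expect_length(back, 3)
  expect_identical(vapply(back, function(s) s$id, character(1)),
                   vapply(cohort, function(s) s$id, character(1)))
  for (i in seq_along(cohort)) {
    expect_equal(back[[i]]$samples, cohort[[i]]$samples, tolerance = 1e-11)
    expect_identical(back[[i]]$label, cohort[[i]]$label)
  }
})

test_that("manifest and signal-file errors are informative", {
  dir <- withr::local_tempdir()
  writeLines(c("id,path,label", "s1,missing.txt,normal"),
             file.path(dir, "man.csv"))
  expect_error(read_manifest(file.path(dir, "man.csv")), "missing.txt")
  writeLines(c("id,path,label", "s1,sig.txt,bad"),
             file.path(dir, "man2.csv"))
  writeLines(c("0.1", "0.2"), file.path(dir, "sig.txt"))
  expect_error(read_manifest(file.path(dir, "man2.csv")), "bad")
  writeLines(c("0.1", "oops", "0.3"), file.path(dir, "corrupt.txt"))
  expect_error(read_signal_file(file.path(dir, "corrupt.txt")), "line 2")
  expect_error(read_manifest(file.path(dir, "nothere.csv")), "nothere")
})

test_that("feature table round trips through CSV", {
  dir <- withr::local_tempdir()
  tab <- data.frame(id = c("a", "b"), label = c("normal", "abnormal"),
                    natom = c(4, 120), tcft = c(0, 3),
                    ff1 = c(1.2, 2.3), ff2 = c(1.1, 2.0),
                    vms = c(0.01, 0.2), mu = c(0.5, 0.49),
                    fd = c(2.1, 1.8))
  fp <- file.path(dir, "feat.csv")
  write_features(fp, tab)
  back <- read_features(fp)
  expect_equal(back, tab)
  expect_error(write_features(fp, tab[, -3]), "columns")
})
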