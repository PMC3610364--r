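# Shared fixtures: reduced-rate study cohort used throughout the tests.
# 1024 samples over the 4 s swing (256 Hz) keeps the wavelet matching
# pursuit tractable while preserving the class structure; the methods
# vignette discusses this choice.
test_cohort_params <- function(seed = 1, n_normal = 51, n_abnormal = 38) {
  cohort_params(n_normal = n_normal, n_abnormal = n_abnormal,
                fs = 256, duration_s = 4, seed = seed)
}

# Two well-separated Gaussian blobs in 2-D.
blob_data <- function(n_per_class = 10, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
  y <- rep(c(-1, 1), each = n_per_class)
  list(x = x, y = y)
}
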