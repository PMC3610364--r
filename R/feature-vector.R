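#' Analysis configuration
#'
#' Collects the tunable parameters of the feature-extraction and
#' classification pipeline. Defaults are the protocol values: 15 dB
#' matching-pursuit stopping SNR, 10th-order 50 Hz Butterworth prefilter
#' with 100-sample delay calibration, turn threshold 0.2, 50 ms VMS
#' segments, polynomial kernel (degree 2, intercept 1), regularization 5,
#' 5 ensemble components, fixed-size-15 subset selection.
#'
#' @param turns.threshold Turns-count amplitude threshold.
#' @param filter.order,filter.fc_hz,filter.delay_samples Butterworth
#'   prefilter parameters.
#' @param mp.snr_stop_db Matching-pursuit stopping SNR (dB).
#' @param mp.wavelet,mp.max_iter Dictionary wavelet and iteration cap.
#' @param vms.segment_s VMS segment length in seconds (converted to samples
#'   at each signal's rate).
#' @param fd.fit_band_hz Spectral-fit band for the fractal dimension, or
#'   `NULL` to choose `c(10, min(500, 0.45 * fs))` per signal.
#' @param detrend If `TRUE`, remove the mean before matching pursuit
#'   (default `FALSE`).
#' @param kernel,gamma Classifier kernel ([kernel_spec()]) and
#'   regularization.
#' @param n_components Ensemble size K.
#' @param subset_size Fixed training-subset size for active selection.
#' @return A list of class `vag_config`.
#' @export
vag_config <- function(turns.threshold = 0.2,
                       filter.order = 10,
                       filter.fc_hz = 50,
                       filter.delay_samples = 100,
                       mp.snr_stop_db = 15,
                       mp.wavelet = "db8",
                       mp.max_iter = 2000,
                       vms.segment_s = 0.05,
                       fd.fit_band_hz = NULL,
                       detrend = FALSE,
                       kernel = kernel_spec("polynomial", degree = 2,
                                            intercept = 1),
                       gamma = 5,
                       n_components = 5,
                       subset_size = 15) {
  structure(as.list(environment()), class = "vag_config")
}

#' Extract the 7-element VAG feature vector
#'
#' Computes, in order: `natom` (matching-pursuit atom count at the stopping
#' SNR, on the raw - optionally detrended - signal), `tcft` (fixed-threshold
#' turns count on the normalized and low-pass filtered signal), `ff1`/`ff2`
#' (form factors of the two halves of the normalized signal), `vms`
#' (variance of segment mean squares), `mu` (Parzen density mean), and `fd`
#' (spectral fractal dimension), the last four on the normalized signal.
#'
#' @param signal A [vag_signal()].
#' @param config A [vag_config()].
#' @return Named numeric vector of length 7:
#'   `natom, tcft, ff1, ff2, vms, mu, fd`.
#' @export
extract_feature_vector <- function(signal, config = vag_config()) {
  stopifnot(inherits(signal, "vag_signal"))
  x_raw <- signal$samples
  if (isTRUE(config$detrend)) x_raw <- x_raw - mean(x_raw)
  fs <- signal$fs
  natom <- natom_feature(x_raw, snr_stop_db = config$mp.snr_stop_db,
                         wavelet = config$mp.wavelet,
                         max_iter = config$mp.max_iter)
  xn <- normalize_amplitude(signal$samples)
  xf <- butterworth_lowpass(xn, fs, order = config$filter.order,
                            fc = config$filter.fc_hz,
                            delay_samples = config$filter.delay_samples)
  tcft <- count_turns_fixed_threshold(xf, threshold = config$turns.threshold)
  ff <- ff_halves(xn)
  seg <- max(2L, round(config$vms.segment_s * fs))
  vms <- variance_of_mean_squared(xn, seg)
  mu <- parzen_pdf_mean(xn)
  fd <- fractal_dimension_psd(xn, fs, fit_band = config$fd.fit_band_hz)
  c(natom = natom, tcft = tcft, ff1 = unname(ff["ff1"]),
    ff2 = unname(ff["ff2"]), vms = vms, mu = mu, fd = fd)
}

#' Feature table for a whole cohort
#'
#' Applies [extract_feature_vector()] to every signal and assembles the
#' standard feature data frame.
#'
#' @param signals List of [vag_signal()] objects.
#' @param config A [vag_config()].
#' @return Data frame with columns
#'   `id, label, natom, tcft, ff1, ff2, vms, mu, fd`.
#' @export
extract_cohort_features <- function(signals, config = vag_config()) {
  rows <- lapply(signals, function(s) {
    fv <- extract_feature_vector(s, config)
    cbind(data.frame(id = s$id, label = s$label, stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classic two-sided Student's t-test with pooled variance, as used for
#' univariate feature screening (significance convention P < 0.01).
#' Degenerate inputs follow limit conventions: zero pooled variance yields
#' `p = 1` for equal means and `p = 0` otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
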