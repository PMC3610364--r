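# Time-domain feature extraction: Butterworth prefiltering with delay
# calibration, the fixed-threshold turns count, Hjorth-style form factors,
# variance of segment mean squares, the Parzen-window density mean, and the
# spectral fractal dimension.

#' Low-pass Butterworth prefilter with delay calibration
#'
#' Applies a forward (causal) IIR low-pass Butterworth filter with unit gain
#' at DC, then compensates the filtering delay by advancing the output by a
#' fixed number of samples, zero-padding the tail. The delay value is a
#' calibration constant of the analysis protocol (100 samples = 0.05 s at
#' 2 kHz), not a computed group delay; it is configurable.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (default 10).
#' @param fc Cutoff frequency in Hz (default 50); must be below `fs / 2`.
#' @param delay_samples Samples to advance the output by (default 100).
#' @return Filtered, delay-compensated numeric vector of the same length.
#' @export
butterworth_lowpass <- function(x, fs, order = 10, fc = 50,
                                delay_samples = 100) {
  if (fc >= fs / 2) stop("cutoff fc must be below the Nyquist rate fs/2")
  bt <- signal::butter(order, fc / (fs / 2), type = "low")
  # exact unit DC gain: scale the numerator so sum(b)/sum(a) == 1
  bt$b <- bt$b * (sum(bt$a) / sum(bt$b))
  y <- as.numeric(signal::filter(bt, x))
  d <- min(as.integer(delay_samples), length(y))
  if (d > 0) y <- c(y[-seq_len(d)], numeric(d))
  y
}

#' Turns count with a fixed amplitude threshold (TCFT)
#'
#' Counts samples that (1) are a change of direction - the sign of the
#' first difference flips, with both neighboring differences non-zero - and
#' (2) differ from the immediately preceding sample by strictly more than
#' `threshold`. Intended for signals normalized to `[0, 1]` and low-pass
#' filtered (see [butterworth_lowpass()]); the default threshold 0.2 is then
#' one fifth of the full dynamic range.
#'
#' @param x Numeric signal (normalized and filtered), length >= 3.
#' @param threshold Amplitude threshold (default 0.2), strict inequality.
#' @return Integer count of significant turns.
#' @examples
#' count_turns_fixed_threshold(c(0, 0.5, 0.1, 0.6, 0.55))  # 3
#' @export
count_turns_fixed_threshold <- function(x, threshold = 0.2) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("turns count needs at least 3 samples")
  d <- diff(x)
  prev <- d[-length(d)]
  nxt <- d[-1]
  sum(prev != 0 & nxt != 0 & sign(prev) != sign(nxt) &
        abs(prev) > threshold)
}

#' Hjorth-style form factor
#'
#' `FF = (sd(x'') / sd(x')) / (sd(x') / sd(x))`, the ratio of waveform
#' complexity to mobility computed from discrete first and second
#' differences. A single densely sampled sinusoid has FF near 1; broadband
#' or multi-component signals have FF > 1. Scale-invariant.
#'
#' @param x Numeric signal, length >= 3 with non-degenerate differences.
#' @return Form factor (dimensionless).
#' @export
form_factor <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("form factor needs at least 3 samples")
  s0 <- stats::sd(x)
  d1 <- diff(x)
  d2 <- diff(d1)
  s1 <- stats::sd(d1)
  s2 <- stats::sd(d2)
  if (s0 == 0 || s1 == 0)
    stop("form factor undefined: zero-variance signal or first difference")
  (s2 / s1) / (s1 / s0)
}

#' Form factors of the two signal halves (FF1, FF2)
#'
#' Splits the signal at the midpoint and computes [form_factor()] on each
#' half; the swing protocol makes the halves correspond to the extension and
#' flexion phases of the leg movement.
#'
#' @param x Numeric signal.
#' @return Named numeric vector `c(ff1 = , ff2 = )`.
#' @export
ff_halves <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 6) stop("signal too short to split into halves")
  mid <- n %/% 2
  c(ff1 = form_factor(x[1:mid]), ff2 = form_factor(x[(mid + 1):n]))
}

#' Variance of segment mean-squared values (VMS)
#'
#' Splits the signal into non-overlapping segments, computes each segment's
#' mean of squares, and returns the unbiased sample variance of those
#' values: a measure of how unevenly signal power is distributed over time.
#'
#' @param x Numeric signal.
#' @param segment_len Segment length in samples; must allow at least two
#'   full segments.
#' @return Variance of the per-segment mean squares (signal units to the 4th
#'   power).
#' @examples
#' variance_of_mean_squared(c(1, 1, 2, 2), 2)  # var(c(1, 4)) = 4.5
#' @export
variance_of_mean_squared <- function(x, segment_len) {
  x <- as.numeric(x)
  segment_len <- as.integer(segment_len)
  if (segment_len > length(x))
    stop("segment_len exceeds the signal length")
  k <- length(x) %/% segment_len
  if (k < 2) stop("need at least 2 full segments for a variance")
  seg <- matrix(x[seq_len(k * segment_len)], nrow = segment_len)
  stats::var(colMeans(seg^2))
}

#' Mean of the Parzen-window amplitude density
#'
#' Estimates the probability density of the signal's amplitude values with a
#' Gaussian-kernel Parzen window and returns the mean of that density by
#' numeric integration. With a zero-mean kernel this equals the sample mean
#' of the amplitudes; the quadrature route is exposed because the density
#' itself is the object of interest in the screening literature.
#'
#' @param x Numeric signal (amplitude values).
#' @param bandwidth Kernel bandwidth; default is Silverman's rule of thumb
#'   ([stats::bw.nrd0()]).
#' @param n_grid Number of quadrature nodes (default 2048).
#' @return The density mean (signal units).
#' @export
parzen_pdf_mean <- function(x, bandwidth = NULL, n_grid = 2048) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("empty signal")
  if (is.null(bandwidth)) {
    bandwidth <- if (length(x) >= 2 && stats::sd(x) > 0)
      stats::bw.nrd0(x) else 0.05
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  lo <- min(x) - 6 * bandwidth
  hi <- max(x) + 6 * bandwidth
  z <- seq(lo, hi, length.out = n_grid)
  dz <- z[2] - z[1]
  # Parzen density: average of Gaussian kernels centered at the samples
  f <- rowMeans(outer(z, x, function(a, b) stats::dnorm(a, b, bandwidth)))
  # trapezoidal moments; renormalize so truncation does not bias the mean
  w <- rep(dz, n_grid); w[c(1, n_grid)] <- dz / 2
  sum(w * z * f) / sum(w * f)
}

#' Spectral fractal dimension (FD)
#'
#' Estimates the power-law exponent `beta` of the signal's power spectral
#' density by least squares on `log(PSD)` versus `log(f)` over `fit_band`
#' (Welch-averaged periodogram, Hann windows, 50% overlap), and returns
#' `FD = (5 - beta) / 2`. For 1/f^beta noise: white noise gives FD near
#' 2.5, Brownian-type (beta = 2) noise gives FD near 1.5.
#'
#' @param x Numeric signal, length >= 64.
#' @param fs Sampling rate in Hz.
#' @param fit_band Frequency band `c(lo, hi)` in Hz for the fit; default
#'   10 Hz up to `min(500, 0.45 * fs)`, excluding DC and the region near
#'   Nyquist. Must lie inside `(0, fs / 2)`.
#' @param nperseg Welch segment length (default `min(256, length(x))`).
#' @return Fractal dimension (dimensionless, unclipped).
#' @export
fractal_dimension_psd <- function(x, fs, fit_band = NULL, nperseg = NULL) {
  x <- as.numeric(x)
  if (length(x) < 64) stop("fractal dimension needs at least 64 samples")
  if (is.null(fit_band)) fit_band <- c(10, min(500, 0.45 * fs))
  if (fit_band[1] <= 0 || fit_band[2] >= fs / 2 ||
      fit_band[1] >= fit_band[2])
    stop("fit_band must lie inside (0, fs/2)")
  ps <- welch_psd(x, fs, nperseg = nperseg)
  sel <- ps$freq >= fit_band[1] & ps$freq <= fit_band[2] & ps$psd > 0
  if (sum(sel) < 4) stop("too few spectral points in fit_band")
  fit <- stats::lm(log(ps$psd[sel]) ~ log(ps$freq[sel]))
  beta <- -unname(stats::coef(fit)[2])
  (5 - beta) / 2
}

#' Welch-averaged power spectral density
#'
#' Hann-windowed segments with 50% overlap, averaged modified periodograms
#' (density scaling: the PSD integrates to the signal variance over
#' `[0, fs/2]` up to windowing loss).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length; default `min(256, length(x))`.
#' @return List with `freq` (Hz, DC excluded) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(256L, n)
  nperseg <- as.integer(nperseg)
  if (nperseg < 8) stop("nperseg too small")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)))
  u <- sum(win^2)
  acc <- numeric(nperseg %/% 2L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / (u * fs)
    acc <- acc + 2 * sp[2:(nperseg %/% 2L + 1L)]
  }
  list(freq = (1:(nperseg %/% 2L)) * fs / nperseg,
       psd = acc / length(starts))
}
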