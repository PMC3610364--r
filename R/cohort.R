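# Synthetic two-class VAG cohort. Real VAG data are not publicly available;
# the generator emulates the qualitative structure reported for clinical
# records: a smooth swing-cycle baseline common to both classes, rare small
# transients in the normal class, and - in the abnormal class - more and
# larger transients, bursts of crepitus-like friction vibration, heavier
# broadband noise, and a weak powerline component.

#' Parameters of the synthetic VAG cohort generator
#'
#' Defaults correspond to the clinical acquisition protocol (4 s leg swing at
#' 2 kHz, 12-bit digitization, 51 normal / 38 abnormal subjects) and to a
#' qualitative reading of published normal/abnormal VAG waveforms. See the
#' methods vignette for the rationale behind each value.
#'
#' @param n_normal,n_abnormal Class sizes (default 51 / 38).
#' @param fs Sampling rate in Hz (default 2000).
#' @param duration_s Swing duration in seconds (default 4; `fs * duration_s`
#'   samples per signal).
#' @param seed Integer seed; cohorts are bit-identical given the seed.
#' @param base_band Frequency band (Hz) of the smooth swing component,
#'   default `c(0.25, 2)`: two sweep cycles with a slow envelope.
#' @param transient_rate_normal,transient_rate_abnormal Expected number of
#'   tap/click transients per signal (Poisson), defaults 4 and 25.
#' @param transient_amp Base transient amplitude in signal units (default 1).
#'   Normal transients are drawn at 0.2-0.6 of this scale, abnormal ones at
#'   0.8-2.0, reflecting larger artifacts in pathological records.
#' @param crepitus_rate_abnormal Expected number of friction-vibration bursts
#'   per abnormal signal (default 6; 0 for normal signals).
#' @param crepitus_amp Amplitude of crepitus bursts relative to the unit
#'   swing (default 3).
#' @param crepitus_band Carrier band of the friction vibration in Hz,
#'   default `c(30, 48)` - the strong sub-50 Hz grinding component that
#'   survives the turns-count prefilter.
#' @param noise_sd_normal,noise_sd_abnormal Broadband (white) noise standard
#'   deviations, defaults 0.03 and 0.15.
#' @param powerline_hz Powerline interference frequency (default 50 Hz),
#'   added at low amplitude to abnormal signals only.
#' @param powerline_amp Powerline amplitude (default 0.05).
#' @param quantization_bits If non-`NULL`, quantize to this many bits over
#'   the full range after synthesis (acquisition used 12 bits). Default
#'   `NULL` (off) so floating-point identities in analyses stay exact.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_normal = 51, n_abnormal = 38, fs = 2000,
                          duration_s = 4, seed = 1,
                          base_band = c(0.25, 2),
                          transient_rate_normal = 4,
                          transient_rate_abnormal = 25,
                          transient_amp = 1,
                          crepitus_rate_abnormal = 6,
                          crepitus_amp = 3,
                          crepitus_band = c(30, 48),
                          noise_sd_normal = 0.03,
                          noise_sd_abnormal = 0.15,
                          powerline_hz = 50,
                          powerline_amp = 0.05,
                          quantization_bits = NULL) {
  if (n_normal < 0 || n_abnormal < 0) stop("cohort sizes must be >= 0")
  if (transient_rate_normal < 0 || transient_rate_abnormal < 0 ||
      crepitus_rate_abnormal < 0)
    stop("event rates must be >= 0")
  if (noise_sd_normal < 0 || noise_sd_abnormal < 0)
    stop("noise standard deviations must be >= 0")
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  structure(as.list(environment()), class = "cohort_params")
}

# One raised-cosine (Hann) event added in place.
.add_hann_burst <- function(x, fs, width_s, amp, carrier_hz = NULL) {
  n <- length(x)
  w <- max(3L, round(width_s * fs))
  if (w >= n) w <- n - 1L
  c0 <- sample.int(n - w, 1)
  env <- 0.5 * (1 - cos(2 * pi * seq(0, w - 1) / (w - 1)))
  burst <- if (is.null(carrier_hz)) {
    amp * env
  } else {
    amp * env * sin(2 * pi * carrier_hz * seq(0, w - 1) / fs)
  }
  x[c0:(c0 + w - 1)] <- x[c0:(c0 + w - 1)] + burst
  x
}

.generate_one <- function(params, abnormal) {
  fs <- params$fs
  n <- round(fs * params$duration_s)
  t <- (0:(n - 1)) / fs
  # smooth swing baseline: two sweep cycles over the record with a slow
  # envelope; frequencies sit inside base_band
  f_swing <- max(params$base_band[1], 2 / params$duration_s)
  f_env <- params$base_band[1]
  x <- sin(2 * pi * f_swing * t) * (0.7 + 0.3 * cos(2 * pi * f_env * t))
  # transients: short raised-cosine taps, mostly one-sided
  rate <- if (abnormal) params$transient_rate_abnormal else
    params$transient_rate_normal
  amp_rng <- if (abnormal) c(0.8, 2.0) else c(0.2, 0.6)
  k <- stats::rpois(1, rate)
  if (k > 0) for (i in seq_len(k)) {
    a <- stats::runif(1, amp_rng[1], amp_rng[2]) * params$transient_amp *
      sample(c(1, 1, -1), 1)
    x <- .add_hann_burst(x, fs, stats::runif(1, 0.005, 0.020), a)
  }
  # crepitus: friction-vibration bursts with a sub-50 Hz carrier
  if (abnormal && params$crepitus_rate_abnormal > 0) {
    nb <- stats::rpois(1, params$crepitus_rate_abnormal)
    if (nb > 0) for (b in seq_len(nb)) {
      x <- .add_hann_burst(
        x, fs, stats::runif(1, 0.05, 0.15),
        stats::runif(1, 0.6, 1.3) * params$crepitus_amp,
        carrier_hz = stats::runif(1, params$crepitus_band[1],
                                  params$crepitus_band[2])
      )
    }
  }
  sd <- if (abnormal) params$noise_sd_abnormal else params$noise_sd_normal
  if (sd > 0) x <- x + stats::rnorm(n, 0, sd)
  if (abnormal && params$powerline_amp > 0 && params$powerline_hz < fs / 2) {
    x <- x + params$powerline_amp *
      sin(2 * pi * params$powerline_hz * t + stats::runif(1, 0, 2 * pi))
  }
  if (!is.null(params$quantization_bits)) {
    levels <- 2^params$quantization_bits - 1
    rng <- range(x)
    if (rng[2] > rng[1]) {
      q <- round((x - rng[1]) / (rng[2] - rng[1]) * levels)
      x <- q / levels * (rng[2] - rng[1]) + rng[1]
    }
  }
  x
}

#' Generate a synthetic two-class VAG cohort
#'
#' Draws `n_normal + n_abnormal` signals under the class-conditional model
#' described in [cohort_params()]. The abnormal class has higher amplitude
#' variability, more and larger transients, crepitus-like vibration bursts,
#' more broadband noise, and a weak powerline component. Deterministic given
#' `params$seed`.
#'
#' @param params A [cohort_params()] object.
#' @return List of [vag_signal()] objects, normal signals first, ids
#'   `N001.., A001..`.
#' @export
generate_synthetic_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed))
  set.seed(params$seed)
  out <- vector("list", params$n_normal + params$n_abnormal)
  i <- 0L
  for (j in seq_len(params$n_normal)) {
    i <- i + 1L
    out[[i]] <- vag_signal(.generate_one(params, FALSE), fs = params$fs,
                           label = "normal", id = sprintf("N%03d", j))
  }
  for (j in seq_len(params$n_abnormal)) {
    i <- i + 1L
    out[[i]] <- vag_signal(.generate_one(params, TRUE), fs = params$fs,
                           label = "abnormal", id = sprintf("A%03d", j))
  }
  out
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
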