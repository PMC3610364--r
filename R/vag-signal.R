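#' A labeled vibroarthrographic (VAG) signal
#'
#' Container for one single-channel knee-joint vibration record: the raw
#' samples (uncalibrated acceleration units), the sampling rate, a class
#' label, and an identifier. The clinical recording convention is a 4 s leg
#' swing (135 degrees to 0 and back) sampled at 2 kHz, i.e. 8000 samples.
#'
#' @param samples Numeric vector, length >= 2, all finite.
#' @param fs Sampling rate in Hz (> 0), default 2000.
#' @param label One of `"normal"`, `"abnormal"`, `"unknown"`.
#' @param id Identifier string.
#' @return An object of class `vag_signal`.
#' @examples
#' s <- vag_signal(sin(seq(0, 8 * pi, length.out = 256)), fs = 256)
#' @export
vag_signal <- function(samples, fs = 2000, label = "unknown", id = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("vag_signal: need at least 2 samples")
  if (!all(is.finite(samples))) stop("vag_signal: all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("vag_signal: fs must be a positive scalar")
  label <- match.arg(label, c("normal", "abnormal", "unknown"))
  structure(
    list(samples = samples, fs = fs, label = label, id = as.character(id)),
    class = "vag_signal"
  )
}

#' @export
print.vag_signal <- function(x, ...) {
  cat("VAG signal '", x$id, "': ", length(x$samples), " samples @ ", x$fs,
      " Hz, label = ", x$label, "\n", sep = "")
  invisible(x)
}

# Label encoding for classifiers: abnormal (diseased) is the positive class.
#' Encode VAG labels as numeric classes
#'
#' Maps `"abnormal"` to `+1` (the positive, diseased class) and `"normal"`
#' to `-1`, following the clinical true-positive convention.
#'
#' @param labels Character vector of `"normal"` / `"abnormal"`.
#' @return Numeric vector of +1 / -1.
#' @export
encode_labels <- function(labels) {
  if (!all(labels %in% c("normal", "abnormal")))
    stop("labels must be 'normal' or 'abnormal'")
  ifelse(labels == "abnormal", 1, -1)
}

#' Amplitude normalization to the unit interval
#'
#' Linearly rescales a signal so its minimum is 0 and its maximum is 1,
#' preserving waveform shape. This is the standard pre-step before the
#' fixed-threshold turns count, so that the 0.2 amplitude threshold is
#' relative to the full dynamic range of the record.
#'
#' @param signal A [vag_signal()] or numeric vector.
#' @return Same type as the input, with samples mapped to `[0, 1]`.
#'   Constant signals are an error: mapping them silently to zero would
#'   fabricate a flat record and corrupt downstream turn counts.
#' @examples
#' normalize_amplitude(c(-1, 0, 1))  # 0, 0.5, 1
#' @export
normalize_amplitude <- function(signal) {
  is_vag <- inherits(signal, "vag_signal")
  x <- if (is_vag) signal$samples else as.numeric(signal)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("normalize_amplitude: constant signal has zero amplitude range")
  y <- (x - rng[1]) / (rng[2] - rng[1])
  if (is_vag) {
    signal$samples <- y
    signal
  } else {
    y
  }
}
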