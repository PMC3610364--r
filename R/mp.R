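# Greedy matching pursuit over the wavelet-packet dictionary with an
# SNR-based stopping rule. Each iteration runs one full analysis of the
# residual, picks the globally largest |inner product| (lexicographic
# (level, node, translate) tie-break), subtracts the projection, and stops
# once the reconstruction reaches the target SNR.

#' Signal-to-noise ratio of a decomposition residual
#'
#' `10 * log10(sum(x^2) / sum(residual^2))`, treating the residual as noise.
#' Returns `Inf` for a zero residual.
#'
#' @param x Original signal (non-zero).
#' @param residual Residual signal of the same length.
#' @return SNR in dB.
#' @examples
#' snr_db(c(1, 1), c(1, 1))  # 0
#' @export
snr_db <- function(x, residual) {
  ex <- sum(x^2)
  if (ex == 0) stop("snr_db: zero input signal")
  er <- sum(residual^2)
  if (er == 0) return(Inf)
  10 * log10(ex / er)
}

#' Matching-pursuit decomposition with SNR stopping
#'
#' Greedy decomposition of `x` onto the wavelet-packet dictionary: at every
#' iteration the atom maximizing the absolute inner product with the current
#' residual is selected (ties broken toward the lowest
#' `(level, node, translate)`), its projection is subtracted, and iteration
#' stops as soon as the SNR of the reconstruction reaches `snr_stop_db`, the
#' residual vanishes, or `max_iter` is hit.
#'
#' The number of iterations `M` is the `Natom` feature: noisier signals need
#' more atoms to reach a fixed SNR.
#'
#' @param x Numeric signal whose length equals `dict$n`; must not be all
#'   zero. Non-dyadic signals should be zero-padded first (see
#'   [natom_feature()]).
#' @param dict A [build_dictionary()] object.
#' @param snr_stop_db Stopping SNR in dB (default 15).
#' @param max_iter Iteration cap (default 2000). Hitting it is not an error;
#'   `stop_reason` records it.
#' @return An object of class `mp_decomposition`: data frame `atoms` with
#'   columns `iter`, `level`, `node`, `translate`, `coefficient`, `snr_db`;
#'   `residual`; `n_iter`; `stop_reason` in
#'   `c("snr_reached", "max_iter", "zero_residual")`; plus the inputs.
#' @export
mp_decompose <- function(x, dict, snr_stop_db = 15, max_iter = 2000) {
  stopifnot(inherits(dict, "wp_dictionary"))
  x <- as.numeric(x)
  if (length(x) != dict$n) stop("signal length does not match dictionary")
  if (all(x == 0)) stop("mp_decompose: zero input signal")
  n <- dict$n
  residual <- x
  lvl <- int_node <- int_tr <- integer(0)
  coefs <- snrs <- numeric(0)
  stop_reason <- "max_iter"
  m <- 0L
  while (m < max_iter) {
    cmat <- wp_analyze(residual, dict)
    acmat <- abs(cmat)
    # cmat is n x depth, so column-major which.max scans level 1 positions
    # first: the first maximum is the lexicographically lowest
    # (level, node, translate) among exact ties.
    best <- which.max(acmat)
    l <- (best - 1L) %/% n + 1L
    pos <- (best - 1L) %% n               # node-major position within level
    node_len <- n %/% 2L^l
    p <- pos %/% node_len
    tr <- pos %% node_len
    a <- cmat[best]
    atom <- wp_atom(dict, l, p, tr)
    residual <- residual - a * atom
    m <- m + 1L
    lvl[m] <- l; int_node[m] <- p; int_tr[m] <- tr; coefs[m] <- a
    er <- sum(residual^2)
    snrs[m] <- if (er == 0) Inf else 10 * log10(sum(x^2) / er)
    if (er <= .Machine$double.eps * sum(x^2)) {
      stop_reason <- "zero_residual"
      break
    }
    if (snrs[m] >= snr_stop_db) {
      stop_reason <- "snr_reached"
      break
    }
  }
  structure(
    list(
      atoms = data.frame(
        iter = seq_len(m), level = lvl, node = int_node,
        translate = int_tr, coefficient = coefs, snr_db = snrs
      ),
      residual = residual,
      n_iter = m,
      stop_reason = stop_reason,
      snr_stop_db = snr_stop_db,
      dict = dict,
      input_energy = sum(x^2)
    ),
    class = "mp_decomposition"
  )
}

#' @export
print.mp_decomposition <- function(x, ...) {
  cat("Matching-pursuit decomposition:", x$n_iter, "atoms, stop:",
      x$stop_reason, "\n")
  if (x$n_iter > 0)
    cat("final SNR:", round(x$atoms$snr_db[x$n_iter], 3), "dB\n")
  invisible(x)
}

#' Reconstruct a signal from its matching-pursuit atoms
#'
#' Sums `a_m * atom_m` over the selected atoms. By construction
#' `reconstruct(d) + d$residual` equals the decomposed input to floating
#' point accuracy.
#'
#' @param decomp An [mp_decompose()] result.
#' @param dict Dictionary; defaults to the one stored in `decomp`.
#' @return Numeric vector of length `dict$n`.
#' @export
reconstruct <- function(decomp, dict = decomp$dict) {
  stopifnot(inherits(decomp, "mp_decomposition"), inherits(dict, "wp_dictionary"))
  out <- numeric(dict$n)
  a <- decomp$atoms
  if (nrow(a) == 0) return(out)
  if (any(a$level > dict$depth) ||
      any(a$node >= 2^a$level) ||
      any(a$translate >= dict$n / 2^a$level))
    stop("atom index outside dictionary")
  for (i in seq_len(nrow(a))) {
    out <- out + a$coefficient[i] *
      wp_atom(dict, a$level[i], a$node[i], a$translate[i])
  }
  out
}

#' Number of matching-pursuit atoms at a fixed SNR (Natom feature)
#'
#' Runs [mp_decompose()] at the configured stopping SNR and returns the
#' iteration count. Signals of non-dyadic length are zero-padded to the next
#' power of two (e.g. 8000 samples to 8192) before decomposition; padding
#' preserves energy, so the stopping rule is unaffected.
#'
#' @param x Numeric signal or [vag_signal()].
#' @param snr_stop_db Stopping SNR in dB (default 15).
#' @param wavelet,depth Dictionary parameters (see [build_dictionary()]);
#'   `depth = NULL` uses the full `log2(N)` levels.
#' @param max_iter Iteration cap.
#' @return Integer atom count `M`.
#' @export
natom_feature <- function(x, snr_stop_db = 15, wavelet = "db8",
                          depth = NULL, max_iter = 2000) {
  if (inherits(x, "vag_signal")) x <- x$samples
  x <- pad_to_pow2(as.numeric(x))
  dict <- build_dictionary(length(x), wavelet, depth)
  mp_decompose(x, dict, snr_stop_db = snr_stop_db, max_iter = max_iter)$n_iter
}

#' Zero-pad a signal to the next power of two
#'
#' @param x Numeric vector.
#' @return `x` unchanged if its length is already a power of two, otherwise
#'   `x` followed by zeros up to the next power of two.
#' @export
pad_to_pow2 <- function(x) {
  n <- length(x)
  if (n < 2) stop("signal too short to pad")
  if (.is_pow2(n)) return(x)
  n2 <- 2^ceiling(log2(n))
  c(x, numeric(n2 - n))
}
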