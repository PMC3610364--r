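# Independent oracles used across the tests.

# Explicit-matrix wavelet-packet dictionary: builds the (N * depth) x N atom
# matrix by chaining dense periodized filter-bank matrices level by level.
# This is a deliberately different construction from the package's
# transform-based path.
oracle_dictionary_matrix <- function(n, wavelet = "db8", depth = log2(n)) {
  filt <- vagfusion:::.wavelet_filter(wavelet)
  analysis_mats <- function(m) {
    ah <- matrix(0, m / 2, m)
    ag <- matrix(0, m / 2, m)
    for (k in 0:(m / 2 - 1)) {
      for (j in seq_along(filt$h)) {
        col <- (2 * k + j - 1) %% m + 1
        ah[k + 1, col] <- ah[k + 1, col] + filt$h[j]
        ag[k + 1, col] <- ag[k + 1, col] + filt$g[j]
      }
    }
    list(ah = ah, ag = ag)
  }
  w_prev <- diag(n)
  blocks <- list()
  for (l in seq_len(depth)) {
    m <- n / 2^(l - 1)
    am <- analysis_mats(m)
    w_cur <- matrix(0, n, n)
    for (b in 0:(2^(l - 1) - 1)) {
      rows_parent <- (b * m + 1):((b + 1) * m)
      rows_low <- (2 * b * (m / 2) + 1):((2 * b + 1) * (m / 2))
      rows_high <- ((2 * b + 1) * (m / 2) + 1):((2 * b + 2) * (m / 2))
      w_cur[rows_low, ] <- am$ah %*% w_prev[rows_parent, , drop = FALSE]
      w_cur[rows_high, ] <- am$ag %*% w_prev[rows_parent, , drop = FALSE]
    }
    blocks[[l]] <- w_cur
    w_prev <- w_cur
  }
  do.call(rbind, blocks)
}

# Brute-force matching pursuit on an explicit dictionary matrix: dense inner
# products and argmax each iteration, first index winning ties (rows are in
# (level, node, translate) order).
oracle_mp <- function(x, dmat, snr_stop_db = 15, max_iter = 200) {
  residual <- x
  rows <- integer(0)
  coefs <- numeric(0)
  for (m in seq_len(max_iter)) {
    ip <- as.numeric(dmat %*% residual)
    r <- which.max(abs(ip))
    rows[m] <- r
    coefs[m] <- ip[r]
    residual <- residual - ip[r] * dmat[r, ]
    er <- sum(residual^2)
    if (er == 0 || 10 * log10(sum(x^2) / er) >= snr_stop_db) break
  }
  list(rows = rows, coefs = coefs, residual = residual)
}

# Map the package's (level, node, translate) atom labels onto oracle matrix
# row numbers.
atom_row_index <- function(n, level, node, translate) {
  as.integer((level - 1) * n + node * (n / 2^level) + translate + 1)
}

# 1/f^beta noise by spectral synthesis with random phases (fixed seed set by
# the caller).
synth_power_law_noise <- function(n, beta, fs) {
  amp <- ((1:(n / 2 - 1)) * fs / n)^(-beta / 2)
  ph <- stats::runif(n / 2 - 1, 0, 2 * pi)
  spec <- complex(modulus = c(0, amp, 0), argument = c(0, ph, 0))
  full <- c(spec, Conj(rev(spec[2:(n / 2)])))
  Re(stats::fft(full, inverse = TRUE))
}

# Steady-state gain of a filtering function at frequency f0: least-squares
# projection of the output onto the quadrature pair, transients excluded.
measured_gain <- function(filter_fun, f0, fs, n = 8192) {
  t <- (0:(n - 1)) / fs
  y <- filter_fun(sin(2 * pi * f0 * t))
  per <- fs / f0
  keep <- seq(ceiling(n / 2), ceiling(n / 2) + floor(floor(n / 4 / per) * per) - 1)
  s <- sin(2 * pi * f0 * t[keep])
  co <- cos(2 * pi * f0 * t[keep])
  sqrt((2 * mean(y[keep] * s))^2 + (2 * mean(y[keep] * co))^2)
}

# Rank-sum AUC with half credit for ties: brute force over all
# positive-negative pairs.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
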