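# Periodized orthogonal wavelet-packet machinery used by the matching-pursuit
# decomposition. No external wavelet dependency: the transform is a chain of
# circular filter-and-downsample steps whose index maps are precomputed per
# (N, filter-length) and cached, so a full analysis over all levels costs
# O(N * F * L) arithmetic in vectorized form.

# Daubechies scaling (low-pass) filters, ascending index, normalized so that
# sum(h^2) = 1 and sum(h) = sqrt(2). "dbK" has K vanishing moments, 2K taps.
.db_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.836516303737469,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.01582910525634931, -0.2840155429615469,
          0.00047248457391328, 0.12874742662047847, -0.01736930100180755,
          -0.04408825393079475, 0.01398102791739828, 0.00874609404740578,
          -0.00487035299345157, -0.00039174037337695, 0.00067544940645057,
          -0.00011747678412477)
)

.is_pow2 <- function(n) n >= 1 && bitwAnd(n, n - 1L) == 0L

.wavelet_filter <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "))
  }
  # quadrature mirror high-pass: g[j] = (-1)^j h[F-1-j]
  f_len <- length(h)
  g <- rev(h) * (-1)^(seq_len(f_len) - 1)
  list(h = h, g = g)
}

# Per-level index maps for the vectorized periodized filter bank.
# At the step from level l-1 (nodes of length m) to level l, Q is an
# (N/2) x F matrix: row r holds, for the r-th child coefficient (node-major
# order), the source indices (2k + j) mod m within its parent node. out_low /
# out_high place each parent's low / high children into the standard
# wavelet-packet layout (children of node b are nodes 2b and 2b + 1).
.wp_plan_cache <- new.env(parent = emptyenv())

.wp_plan <- function(n, wavelet, depth) {
  key <- paste(n, wavelet, depth, sep = "|")
  cached <- .wp_plan_cache[[key]]
  if (!is.null(cached)) return(cached)
  filt <- .wavelet_filter(wavelet)
  f_len <- length(filt$h)
  half_f <- f_len %/% 2L
  steps <- vector("list", depth)
  for (l in seq_len(depth)) {
    m <- n %/% 2L^(l - 1L)              # parent node length
    half <- m %/% 2L
    r <- 0:(n %/% 2L - 1L)
    b <- r %/% half                      # parent node id
    k <- r %% half                       # child coefficient within node
    q <- matrix(0L, n %/% 2L, f_len)
    for (j in seq_len(f_len)) {
      q[, j] <- b * m + (2L * k + (j - 1L)) %% m + 1L
    }
    # inverse gather: parent[i] receives h[j]*low[k] (and g[j]*high[k]) for
    # the F/2 taps j of matching parity, j = (i mod 2) + 2c,
    # k = ((i - j)/2) mod (m/2)
    i_all <- 0:(n - 1L)
    bi <- i_all %/% m                    # node id of parent position
    pi_ <- i_all %% m                    # position within parent node
    inv_idx <- matrix(0L, n, half_f)
    hmat <- matrix(0, n, half_f)
    gmat <- matrix(0, n, half_f)
    for (cc in 0:(half_f - 1L)) {
      j <- pi_ %% 2L + 2L * cc
      kk <- ((pi_ - j) %/% 2L) %% half
      inv_idx[, cc + 1L] <- bi * half + kk + 1L  # index into node-major child
      hmat[, cc + 1L] <- filt$h[j + 1L]
      gmat[, cc + 1L] <- filt$g[j + 1L]
    }
    steps[[l]] <- list(
      q = q,
      out_low = b * m + k + 1L,
      out_high = b * m + half + k + 1L,
      inv_idx = inv_idx, hmat = hmat, gmat = gmat
    )
  }
  plan <- list(steps = steps, filt = filt, n = n, depth = depth)
  .wp_plan_cache[[key]] <- plan
  plan
}

#' Wavelet-packet dictionary specification
#'
#' Describes the overcomplete dictionary of periodized orthonormal
#' wavelet-packet atoms used by [mp_decompose()]: for each decomposition level
#' `1..depth` the full set of `N` basis functions (2^l frequency nodes times
#' `N / 2^l` translates), giving `P = N * depth` unit-norm atoms in total.
#' Atoms are addressed by `(level, node, translate)` with zero-based node and
#' translate indices.
#'
#' The dictionary is never materialized as a matrix here; inner products with
#' every atom are obtained by running the wavelet-packet transform
#' ([wp_analyze()]), and individual atoms are synthesized on demand
#' ([wp_atom()]). Use [dictionary_matrix()] to materialize a small dictionary
#' explicitly.
#'
#' @param n Signal length; must be a power of two (callers zero-pad, see
#'   [mp_decompose()]).
#' @param wavelet Daubechies filter name: one of `"db1"`, `"db2"`, `"db4"`,
#'   `"db8"` (default, 16 taps).
#' @param depth Number of levels, between 1 and `log2(n)` (default).
#' @return An object of class `wp_dictionary` with fields `n`, `wavelet`,
#'   `depth`, `n_atoms`.
#' @examples
#' d <- build_dictionary(64, "db8")
#' d$n_atoms  # 64 * 6
#' @export
build_dictionary <- function(n, wavelet = "db8", depth = NULL) {
  if (length(n) != 1 || n < 2 || n != round(n) || !.is_pow2(as.integer(n)))
    stop("dictionary length 'n' must be a power of two (pad the signal first)")
  n <- as.integer(n)
  max_depth <- as.integer(round(log2(n)))
  if (is.null(depth)) depth <- max_depth
  depth <- as.integer(depth)
  if (depth < 1 || depth > max_depth)
    stop("depth must lie in [1, log2(n)] = [1, ", max_depth, "]")
  .wavelet_filter(wavelet)  # validate name
  structure(
    list(n = n, wavelet = wavelet, depth = depth, n_atoms = n * depth),
    class = "wp_dictionary"
  )
}

#' @export
print.wp_dictionary <- function(x, ...) {
  cat("Wavelet-packet dictionary: N =", x$n, ", wavelet =", x$wavelet,
      ", depth =", x$depth, ", atoms =", x$n_atoms, "\n")
  invisible(x)
}

#' Full wavelet-packet analysis over all levels
#'
#' Computes, for every level `1..depth`, the complete set of `N`
#' wavelet-packet coefficients of `x` (periodized boundary handling). Because
#' the per-level transforms are orthonormal, row `l` holds the inner products
#' of `x` with every atom of level `l` in node-major order (node 0 translates
#' first).
#'
#' @param x Numeric vector of length `dict$n`.
#' @param dict A [build_dictionary()] object.
#' @return An `n x depth` numeric matrix; column `l` holds level `l`
#'   coefficients in node-major order.
#' @export
wp_analyze <- function(x, dict) {
  stopifnot(inherits(dict, "wp_dictionary"))
  if (length(x) != dict$n) stop("signal length does not match dictionary")
  plan <- .wp_plan(dict$n, dict$wavelet, dict$depth)
  h <- plan$filt$h
  g <- plan$filt$g
  out <- matrix(0, dict$n, dict$depth)
  cur <- as.numeric(x)
  for (l in seq_len(dict$depth)) {
    st <- plan$steps[[l]]
    gathered <- cur[st$q]
    dim(gathered) <- dim(st$q)
    nxt <- numeric(dict$n)
    nxt[st$out_low] <- gathered %*% h
    nxt[st$out_high] <- gathered %*% g
    out[, l] <- nxt
    cur <- nxt
  }
  out
}

#' Synthesize a single wavelet-packet atom
#'
#' Returns the time-domain waveform of the atom `(level, node, translate)`
#' (zero-based `node`, `translate`) by inverse-transforming a unit
#' coefficient. Atoms are exactly unit norm.
#'
#' @inheritParams wp_analyze
#' @param level Level in `1..dict$depth`.
#' @param node Node (frequency band) index in `0..2^level - 1`.
#' @param translate Translate index in `0..n / 2^level - 1`.
#' @return Numeric vector of length `dict$n`.
#' @export
wp_atom <- function(dict, level, node, translate) {
  stopifnot(inherits(dict, "wp_dictionary"))
  if (level < 1 || level > dict$depth) stop("atom level outside dictionary")
  m <- dict$n %/% 2L^level
  if (node < 0 || node >= 2L^level) stop("atom node outside dictionary")
  if (translate < 0 || translate >= m) stop("atom translate outside dictionary")
  # A unit coefficient lives in a single node, and the inverse step maps
  # children 2b, 2b + 1 onto parent b only: every other node stays zero, so
  # it suffices to carry one node (length m doubling per step) upward.
  filt <- .wavelet_filter(dict$wavelet)
  half_f <- length(filt$h) %/% 2L
  v <- numeric(m)
  v[translate + 1L] <- 1
  p <- as.integer(node)
  for (l in rev(seq_len(level))) {
    mm <- length(v)
    fv <- if (p %% 2L == 0L) filt$h else filt$g
    i2 <- 0:(2L * mm - 1L)
    par_j <- i2 %% 2L
    acc <- numeric(2L * mm)
    for (cc in 0:(half_f - 1L)) {
      jj <- par_j + 2L * cc
      kk <- ((i2 - jj) %/% 2L) %% mm
      acc <- acc + fv[jj + 1L] * v[kk + 1L]
    }
    v <- acc
    p <- p %/% 2L
  }
  v
}

# Inverse-transform a full level-l coefficient layout back to the signal.
.wp_inverse_from <- function(coef, level, dict) {
  plan <- .wp_plan(dict$n, dict$wavelet, dict$depth)
  cur <- coef
  for (l in rev(seq_len(level))) {
    st <- plan$steps[[l]]
    low <- cur[st$out_low]
    high <- cur[st$out_high]
    lg <- low[st$inv_idx]
    dim(lg) <- dim(st$inv_idx)
    hg <- high[st$inv_idx]
    dim(hg) <- dim(st$inv_idx)
    cur <- rowSums(lg * st$hmat + hg * st$gmat)
  }
  cur
}

#' Materialize a dictionary as an explicit atom matrix
#'
#' Builds the full `(n * depth) x n` matrix whose rows are the dictionary
#' atoms, ordered by level, then node, then translate. Intended for
#' inspection and for small problems; memory grows as `n^2 * depth`.
#'
#' @inheritParams wp_analyze
#' @return Numeric matrix; row `(level - 1) * n + node * (n / 2^level) +
#'   translate + 1` is atom `(level, node, translate)`.
#' @export
dictionary_matrix <- function(dict) {
  stopifnot(inherits(dict, "wp_dictionary"))
  if (dict$n * dict$depth > 1e6)
    stop("dictionary too large to materialize; use wp_analyze/wp_atom")
  out <- matrix(0, dict$n * dict$depth, dict$n)
  row <- 1L
  for (l in seq_len(dict$depth)) {
    m <- dict$n %/% 2L^l
    for (p in 0:(2L^l - 1L)) {
      for (t in 0:(m - 1L)) {
        out[row, ] <- wp_atom(dict, l, p, t)
        row <- row + 1L
      }
    }
  }
  out
}
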