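# Active selection of fixed-size training subsets by quadratic Renyi
# entropy maximization: random swap proposals between the working subset and
# the candidate pool, accepted only when the entropy strictly increases.

#' Quadratic Renyi entropy of a sample (Parzen estimate)
#'
#' `H2 = -log( (1/n^2) * sum_ij kappa(x_i - x_j) )` where `kappa` is the
#' Gaussian convolution kernel of the Parzen density estimate: a Gaussian
#' with variance `2 * bandwidth^2` per dimension. Larger values indicate a
#' more spread-out, informative sample.
#'
#' @param x Numeric matrix (rows = samples) or vector.
#' @param bandwidth Positive kernel bandwidth; default is Silverman's
#'   multivariate rule on the (already standardized) features,
#'   `(4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))`.
#' @return Scalar entropy (nats).
#' @export
quadratic_renyi_entropy <- function(x, bandwidth = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 1) stop("empty sample")
  if (is.null(bandwidth))
    bandwidth <- (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  s2 <- 2 * bandwidth^2
  d2 <- as.matrix(stats::dist(x))^2
  k <- exp(-d2 / (2 * s2)) / (2 * pi * s2)^(d / 2)
  -log(sum(k) / n^2)
}

#' Active selection of a fixed-size subset by entropy maximization
#'
#' Starts from a random subset of size `m`; at each step one random
#' candidate from the pool is proposed to replace one random member of the
#' working subset, and the swap is accepted iff the quadratic Renyi entropy
#' strictly increases. Stops after `max_steps` proposals or after
#' `stall_limit` consecutive rejections. Features are standardized before
#' entropy evaluation.
#'
#' @param x Feature matrix (rows = samples).
#' @param m Subset size (default 15). `m == n` returns all indices.
#' @param max_steps Proposal budget (default 500).
#' @param seed Integer seed; runs are deterministic given the seed.
#' @param stall_limit Consecutive-rejection stop (default 100).
#' @param bandwidth Passed to [quadratic_renyi_entropy()].
#' @return An object of class `selection_trace`: `selected` (indices),
#'   `entropy` (value after each accepted step, first entry the initial
#'   subset), `trace` data frame with columns
#'   `step, proposed_in, proposed_out, accepted, entropy`, and
#'   `n_accepted`.
#' @export
active_select_fixed_size <- function(x, m = 15, max_steps = 500, seed = 1,
                                     stall_limit = 100, bandwidth = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (m > n) stop("subset size m exceeds the number of samples")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (m == n) {
    return(structure(
      list(selected = seq_len(n),
           entropy = quadratic_renyi_entropy(xs, bandwidth),
           trace = data.frame(step = integer(0), proposed_in = integer(0),
                              proposed_out = integer(0),
                              accepted = logical(0), entropy = numeric(0)),
           n_accepted = 0L, seed = seed),
      class = "selection_trace"
    ))
  }
  if (max_steps < 1) stop("max_steps must be >= 1")
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed))
  set.seed(seed)
  work <- sample.int(n, m)
  pool <- setdiff(seq_len(n), work)
  h <- quadratic_renyi_entropy(xs[work, , drop = FALSE], bandwidth)
  ent <- h
  steps <- vector("list", max_steps)
  stall <- 0L
  n_acc <- 0L
  for (s in seq_len(max_steps)) {
    cand <- pool[sample.int(length(pool), 1)]
    out <- work[sample.int(m, 1)]
    trial <- c(setdiff(work, out), cand)
    h_new <- quadratic_renyi_entropy(xs[trial, , drop = FALSE], bandwidth)
    acc <- h_new > h
    if (acc) {
      pool <- c(setdiff(pool, cand), out)
      work <- trial
      h <- h_new
      ent <- c(ent, h)
      n_acc <- n_acc + 1L
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    steps[[s]] <- data.frame(step = s, proposed_in = cand,
                             proposed_out = out, accepted = acc,
                             entropy = h)
    if (stall >= stall_limit) break
  }
  structure(
    list(selected = sort(work), entropy = ent,
         trace = do.call(rbind, steps[!vapply(steps, is.null, logical(1))]),
         n_accepted = n_acc, seed = seed),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Entropy-based subset selection:", length(x$selected), "indices,",
      x$n_accepted, "accepted swaps, final entropy",
      round(x$entropy[length(x$entropy)], 4), "\n")
  invisible(x)
}
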