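# Ensembles of component LS-SVMs: bootstrap aggregation (Bagging) and the
# dynamic weighted fusion (DWF) rule, whose per-sample weights are inversely
# proportional to the component errors with a closed-form normalization.

#' Ensemble configuration
#'
#' @param k Number of component classifiers (default 5).
#' @param dwf_mode `"oracle"` (errors from the true label, the published
#'   evaluation protocol - not deployable without labels) or `"estimated"`
#'   (each component's mean absolute validation error, constant per
#'   component).
#' @param error_transform `"absolute"` (default: weights computed from
#'   |e_k|, preserving nonnegativity and normalization) or `"signed"` (the
#'   literal signed-error formula, which can produce negative or undefined
#'   weights; provided for study).
#' @param epsilon Threshold below which an error magnitude is treated as
#'   zero (default 1e-12); zero-error components absorb all weight.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(k = 5, dwf_mode = c("oracle", "estimated"),
                            error_transform = c("absolute", "signed"),
                            epsilon = 1e-12) {
  if (k < 1) stop("ensemble needs at least one component")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(k = as.integer(k), dwf_mode = match.arg(dwf_mode),
                 error_transform = match.arg(error_transform),
                 epsilon = epsilon),
            class = "ensemble_config")
}

#' Train component LS-SVMs on bootstrap resamples
#'
#' Each component is trained on a with-replacement resample of the full
#' training-set size. Resamples that happen to contain one class only are
#' redrawn (at most 100 attempts each). Deterministic given `seed`.
#'
#' @param x Feature matrix, rows = samples.
#' @param y Labels +1 / -1.
#' @param k Number of components (default 5).
#' @param seed Integer seed.
#' @param kernel,gamma Passed to [train_lssvm()].
#' @return List of `k` [train_lssvm()] models; each carries its bootstrap
#'   indices as attribute `"indices"`.
#' @export
bagging_train <- function(x, y, k = 5, seed = 1,
                          kernel = kernel_spec(), gamma = 5) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 2 || length(unique(y)) < 2)
    stop("need at least two samples with both classes")
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed))
  set.seed(seed)
  models <- vector("list", k)
  for (j in seq_len(k)) {
    idx <- NULL
    for (attempt in 1:100) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[cand])) == 2) { idx <- cand; break }
    }
    if (is.null(idx))
      stop("could not draw a two-class bootstrap sample in 100 attempts")
    m <- train_lssvm(x[idx, , drop = FALSE], y[idx], kernel, gamma)
    attr(m, "indices") <- idx
    models[[j]] <- m
  }
  models
}

#' Simple-average (Bagging) ensemble output
#'
#' Arithmetic mean of the component decision values; the predicted class is
#' its sign (ties to +1).
#'
#' @param models Non-empty list of [train_lssvm()] models.
#' @param x Feature vector or matrix of rows.
#' @return Numeric averaged decision value(s).
#' @export
bagging_predict <- function(models, x) {
  if (length(models) == 0) stop("empty model list")
  g <- vapply(models, decision_value, numeric(NROW(x)),
              x = if (is.matrix(x)) x else matrix(x, nrow = 1))
  if (is.null(dim(g))) mean(g) else rowMeans(g)
}

# Apply the configured error transform; returns magnitudes for "absolute".
.dwf_transform <- function(errors, config) {
  if (config$error_transform == "absolute") abs(errors) else errors
}

#' Dynamic fusion weights from component errors
#'
#' Computes the closed-form fusion weights
#' `w_k = sum_j e_k^-1 e_j^-1 / sum_i sum_j e_i^-1 e_j^-1`
#' (which simplifies to `e_k^-1 / sum_j e_j^-1`), evaluated by the double
#' sum. In the default `"absolute"` mode the errors enter as magnitudes, so
#' the weights are nonnegative and sum to one. Components whose error
#' magnitude is at most `epsilon` take the zero-error limit: all weight is
#' split equally among them.
#'
#' @param errors Numeric vector of component errors `e_k` (length K >= 1).
#' @param config An [ensemble_config()].
#' @return Weight vector summing to 1.
#' @examples
#' dwf_weights(c(1, 2))  # 2/3, 1/3
#' @export
dwf_weights <- function(errors, config = ensemble_config()) {
  k <- length(errors)
  if (k == 0) stop("no component errors supplied")
  e <- .dwf_transform(errors, config)
  zero <- abs(e) <= config$epsilon
  if (any(zero)) {
    w <- numeric(k)
    w[zero] <- 1 / sum(zero)
    return(w)
  }
  inv <- 1 / e
  num <- inv * sum(inv)              # row sums of the double-sum numerator
  num / sum(outer(inv, inv))
}

#' DWF ensemble squared error (closed form)
#'
#' Evaluates the closed-form ensemble squared error
#' `e_DWF^2 = 1 / (sum_i sum_j e_i^-1 e_j^-1) = 1 / (sum e^-1)^2` on the
#' transformed errors. Near-zero errors return 0 (the limit) with attribute
#' `"zero_error" = TRUE`. Note this printed closed form is not equal to the
#' weighted double sum `sum_kj w_k w_j e_k e_j` evaluated at the closed-form
#' weights - the two differ by a factor `K^2`; see
#' [dwf_weighted_squared_error()] and the methods vignette.
#'
#' @inheritParams dwf_weights
#' @return Scalar ensemble squared error.
#' @examples
#' dwf_ensemble_error(c(1, 2))  # 1 / (1.5)^2 = 4/9
#' @export
dwf_ensemble_error <- function(errors, config = ensemble_config()) {
  if (length(errors) == 0) stop("no component errors supplied")
  e <- .dwf_transform(errors, config)
  if (any(abs(e) <= config$epsilon))
    return(structure(0, zero_error = TRUE))
  1 / sum(outer(1 / e, 1 / e))
}

#' Weighted double-sum squared error
#'
#' The quadratic form `sum_k sum_j w_k w_j e_k e_j` for given weights and
#' errors: the other side of the ensemble-error identity, exposed for
#' inspection alongside [dwf_ensemble_error()].
#'
#' @param errors Component errors.
#' @param weights Fusion weights.
#' @return Scalar quadratic-form value.
#' @export
dwf_weighted_squared_error <- function(errors, weights) {
  if (length(errors) != length(weights)) stop("length mismatch")
  as.numeric((weights %*% errors)^2)
}

#' Dynamic weighted fusion of component classifiers
#'
#' Scores each row of `x` with every component, forms per-sample errors
#' (oracle mode: `e_k = label - g_k`, requiring the true labels; estimated
#' mode: each component's supplied constant error estimate), computes the
#' fusion weights, and returns the weighted combination
#' `g_DWF = sum_k w_k g_k` together with the full per-sample breakdown.
#'
#' @param models List of K component models.
#' @param x Feature matrix (rows = samples).
#' @param labels True labels +1 / -1 (oracle mode only).
#' @param error_estimates Length-K positive error estimates (estimated mode
#'   only), e.g. mean absolute validation errors.
#' @param config An [ensemble_config()].
#' @return An object of class `fusion_result`: data frame `per_sample` with
#'   `g_dwf` and `e2_dwf`, plus matrices `g` (outputs), `e` (errors), `w`
#'   (weights).
#' @export
dwf_predict <- function(models, x, labels = NULL, error_estimates = NULL,
                        config = ensemble_config()) {
  k <- length(models)
  if (k == 0) stop("empty model list")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- nrow(x)
  g <- vapply(models, decision_value, numeric(n), x = x)
  g <- matrix(g, nrow = n)
  if (config$dwf_mode == "oracle") {
    if (is.null(labels))
      stop("oracle-mode fusion requires the true labels")
    e <- matrix(labels, n, k) - g
  } else {
    if (is.null(error_estimates) || length(error_estimates) != k)
      stop("estimated-mode fusion requires one error estimate per model")
    e <- matrix(error_estimates, n, k, byrow = TRUE)
  }
  w <- t(apply(e, 1, dwf_weights, config = config))
  w <- matrix(w, nrow = n)
  g_dwf <- rowSums(w * g)
  e2 <- apply(e, 1, function(ei) as.numeric(dwf_ensemble_error(ei, config)))
  structure(
    list(per_sample = data.frame(g_dwf = g_dwf, e2_dwf = e2),
         g = g, e = e, w = w, config = config),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("DWF fusion:", nrow(x$g), "samples,", ncol(x$g), "components, mode:",
      x$config$dwf_mode, "\n")
  invisible(x)
}

#' Export a fusion breakdown as a CSV report
#'
#' Columns: `id`, `label`, `g_1..g_K`, `e_1..e_K`, `w_1..w_K`, `g_dwf`,
#' `e2_dwf`.
#'
#' @param fusion A [dwf_predict()] result.
#' @param ids Sample identifiers.
#' @param labels Numeric labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fusion_report <- function(fusion, ids, labels, path) {
  k <- ncol(fusion$g)
  df <- data.frame(id = ids, label = labels)
  for (j in seq_len(k)) df[[paste0("g_", j)]] <- fusion$g[, j]
  for (j in seq_len(k)) df[[paste0("e_", j)]] <- fusion$e[, j]
  for (j in seq_len(k)) df[[paste0("w_", j)]] <- fusion$w[, j]
  df$g_dwf <- fusion$per_sample$g_dwf
  df$e2_dwf <- fusion$per_sample$e2_dwf
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
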