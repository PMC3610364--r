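# Least-squares support vector machine. Training solves the KKT linear
# system of the equality-constrained regularized least-squares problem
#   [ 0   1^T          ] [ b     ]   [ 0 ]
#   [ 1   Omega + I/g  ] [ alpha ] = [ y ]
# with Omega the kernel Gram matrix and y the +/-1 labels, so the dual
# coefficients satisfy sum(alpha) = 0 through the bias row.

#' Kernel specification
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @param degree Polynomial degree (default 2).
#' @param intercept Polynomial/sigmoid additive constant (default 1).
#' @param width RBF width (sigma, default 1); must be positive.
#' @param slope Sigmoid slope (default 1).
#' @return A list of class `kernel_spec`.
#' @examples
#' kernel_spec("polynomial", degree = 2, intercept = 1)
#' @export
kernel_spec <- function(kind = c("polynomial", "linear", "rbf", "sigmoid"),
                        degree = 2, intercept = 1, width = 1, slope = 1) {
  kind <- match.arg(kind)
  if (kind == "polynomial" && (degree < 1 || degree != round(degree)))
    stop("polynomial degree must be a positive integer")
  if (kind == "rbf" && width <= 0) stop("rbf width must be positive")
  structure(list(kind = kind, degree = degree, intercept = intercept,
                 width = width, slope = slope),
            class = "kernel_spec")
}

#' Evaluate a kernel on two feature vectors
#'
#' @param spec A [kernel_spec()].
#' @param u,v Numeric vectors of equal length.
#' @return Scalar kernel value; symmetric in `u`, `v`.
#' @examples
#' kernel_eval(kernel_spec("polynomial"), c(1, 0), c(1, 0))  # (1 + 1)^2 = 4
#' @export
kernel_eval <- function(spec, u, v) {
  if (length(u) != length(v)) stop("kernel_eval: dimension mismatch")
  .kernel_cross(spec, matrix(u, 1), matrix(v, 1))[1, 1]
}

# Kernel matrix between the rows of A (n x d) and B (m x d).
.kernel_cross <- function(spec, a, b) {
  switch(spec$kind,
    linear = a %*% t(b),
    polynomial = (a %*% t(b) + spec$intercept)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
      exp(-pmax(d2, 0) / (2 * spec$width^2))
    },
    sigmoid = tanh(spec$slope * (a %*% t(b)) + spec$intercept)
  )
}

#' Train a least-squares SVM
#'
#' Standardizes the features to zero mean and unit variance (statistics
#' stored in the model and reapplied at prediction), builds the kernel Gram
#' matrix, and solves the KKT system by a dense direct solve. The
#' regularization `gamma` weights the squared-error term; larger values fit
#' the training labels more tightly.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels, +1 / -1, both classes present.
#' @param kernel A [kernel_spec()] (default polynomial, degree 2,
#'   intercept 1).
#' @param gamma Regularization parameter (default 5).
#' @return An object of class `lssvm_model` with dual coefficients `alpha`,
#'   bias `b`, the standardized training matrix, and the preprocessing
#'   statistics.
#' @export
train_lssvm <- function(x, y, kernel = kernel_spec(), gamma = 5) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree")
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 / -1")
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  if (!all(is.finite(x))) stop("non-finite features")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  n <- nrow(xs)
  omega <- .kernel_cross(kernel, xs, xs)
  a_mat <- rbind(c(0, rep(1, n)),
                 cbind(1, omega + diag(n) / gamma))
  rhs <- c(0, y)
  sol <- tryCatch(solve(a_mat, rhs), error = function(e) {
    stop("singular KKT system (reciprocal condition number ~ ",
         format(rcond(a_mat), digits = 3), "): ", conditionMessage(e))
  })
  structure(
    list(alpha = sol[-1], b = sol[1], x_train = xs, y = y,
         kernel = kernel, gamma = gamma, center = ctr, scale = scl),
    class = "lssvm_model"
  )
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat("LS-SVM:", nrow(x$x_train), "training points,", x$kernel$kind,
      "kernel, gamma =", x$gamma, "\n")
  invisible(x)
}

#' Decision value and class of an LS-SVM
#'
#' `decision_value` computes `g(x) = sum_i alpha_i K(x_i, x) + b` on the
#' standardized input; `classify` returns `sign(g)` with the tie `g == 0`
#' resolved to +1.
#'
#' @param model A trained [train_lssvm()] model.
#' @param x Feature vector or matrix of rows to score.
#' @return Numeric decision value(s), or class label(s) +1 / -1.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "lssvm_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(model$center))
    stop("decision_value: dimension mismatch")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  k <- .kernel_cross(model$kernel, xs, model$x_train)
  as.numeric(k %*% model$alpha + model$b)
}

#' @rdname decision_value
#' @export
classify <- function(model, x) {
  g <- decision_value(model, x)
  ifelse(g >= 0, 1, -1)
}

#' Leave-one-out evaluation of an LS-SVM configuration
#'
#' Retrains the model `n` times, each time holding out one sample, and
#' scores it on the held-out point.
#'
#' @inheritParams train_lssvm
#' @return List with `accuracy` (fraction correct), `decision_values`
#'   (length `n`, held-out scores), `predictions`.
#' @export
loo_evaluate <- function(x, y, kernel = kernel_spec(), gamma = 5) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 4) stop("leave-one-out needs at least 4 samples")
  if (sum(y == 1) < 2 || sum(y == -1) < 2)
    stop("each class needs at least 2 members")
  g <- numeric(n)
  for (i in seq_len(n)) {
    m <- train_lssvm(x[-i, , drop = FALSE], y[-i], kernel, gamma)
    g[i] <- decision_value(m, x[i, , drop = FALSE])
  }
  pred <- ifelse(g >= 0, 1, -1)
  list(accuracy = mean(pred == y), decision_values = g, predictions = pred)
}

#' Serialize / restore an LS-SVM model as JSON
#'
#' @param model A [train_lssvm()] model.
#' @param path JSON file path.
#' @return `lssvm_to_json` returns `path` invisibly; `lssvm_from_json`
#'   returns the model.
#' @export
lssvm_to_json <- function(model, path) {
  stopifnot(inherits(model, "lssvm_model"))
  obj <- list(kernel = unclass(model$kernel), gamma = model$gamma,
              alpha = model$alpha, b = model$b,
              center = model$center, scale = model$scale,
              x_train = model$x_train, y = model$y)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname lssvm_to_json
#' @export
lssvm_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(alpha = as.numeric(obj$alpha), b = as.numeric(obj$b),
         x_train = as.matrix(obj$x_train), y = as.numeric(obj$y),
         kernel = structure(obj$kernel, class = "kernel_spec"),
         gamma = obj$gamma, center = as.numeric(obj$center),
         scale = as.numeric(obj$scale)),
    class = "lssvm_model"
  )
}
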