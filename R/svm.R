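#' Kernel specification for the SVM
#'
#' The three standard kernel families:
#' linear `K(u, v) = u . v`; polynomial `K(u, v) = (u . v + c)^d`;
#' Gaussian RBF `K(u, v) = exp(-||u - v||^2 / (2 sigma^2))`.
#'
#' @param family one of `"linear"`, `"polynomial"`, `"rbf"`.
#' @param c polynomial offset (default 0).
#' @param d polynomial degree, integer >= 1 (default 2).
#' @param sigma RBF bandwidth, > 0 (default 1).
#' @return an object of class `svm_kernel`.
#' @export
svm_kernel <- function(family = c("linear", "polynomial", "rbf"),
                       c = 0, d = 2L, sigma = 1) {
  family <- match.arg(family)
  if (family == "polynomial" && (d < 1 || d != round(d)))
    stop("polynomial degree `d` must be an integer >= 1", call. = FALSE)
  if (family == "rbf" && sigma <= 0)
    stop("RBF `sigma` must be > 0", call. = FALSE)
  structure(list(family = family, c = c, d = as.integer(d), sigma = sigma),
            class = "svm_kernel")
}

#' Evaluate a kernel on a pair of feature vectors
#'
#' @param spec an [svm_kernel()].
#' @param xi,xj numeric vectors of equal length.
#' @return the scalar kernel value.
#' @export
kernel_eval <- function(spec, xi, xj) {
  stopifnot(inherits(spec, "svm_kernel"))
  if (length(xi) != length(xj))
    stop("feature vectors must have equal dimension", call. = FALSE)
  switch(spec$family,
         linear = sum(xi * xj),
         polynomial = (sum(xi * xj) + spec$c)^spec$d,
         rbf = exp(-sum((xi - xj)^2) / (2 * spec$sigma^2)))
}

# Kernel matrix K(X, Y): rows of X against rows of Y.
kernel_matrix <- function(spec, X, Y = X) {
  G <- tcrossprod(X, Y)
  switch(spec$family,
         linear = G,
         polynomial = (G + spec$c)^spec$d,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
           exp(-pmax(d2, 0) / (2 * spec$sigma^2))
         })
}

# --- SMO dual solver -------------------------------------------------------
#
# Maximizes the Wolfe dual
#   Q(alpha) = sum(alpha) - (1/2) sum_ij alpha_i alpha_j y_i y_j K_ij
# subject to 0 <= alpha_i <= C and sum(alpha_i y_i) = 0, by maximal-violating
# -pair coordinate ascent (the working-set selection of standard SMO
# implementations). Deterministic: ties in the pair selection break toward
# the lowest index. Stops when the KKT violation m - M <= tol.
smo_solve <- function(K, y, C, tol = 1e-6, max_iter = 200000L) {
  n <- length(y)
  alpha <- numeric(n)
  grad <- rep(-1, n)                 # gradient of (1/2)a'Qa - sum(a)
  eps <- 1e-12 * max(C, 1)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    yg <- -y * grad
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    m <- yg[i]; M <- yg[j]
    if (m - M <= tol || iter > max_iter) break
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad < 1e-12) quad <- 1e-12
    step <- (m - M) / quad
    # box limits along the feasible direction (alpha_i += y_i*step,
    # alpha_j -= y_j*step keeps the equality constraint)
    lim_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    lim_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    step <- min(step, lim_i, lim_j)
    if (step <= 0) break
    alpha[i] <- alpha[i] + y[i] * step   # direction preserves sum(alpha*y)
    alpha[j] <- alpha[j] - y[j] * step
    grad <- grad + y * step * (K[, i] - K[, j])
  }
  if (iter > max_iter)
    warning("SMO reached the iteration cap before meeting the tolerance")

  free <- alpha > eps & alpha < C - eps
  h <- y * (grad + 1)                # f(x_i) without bias
  if (any(free)) {
    b <- mean(y[free] - h[free])
  } else {
    yg <- -y * grad
    up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    lo <- (y > 0 & alpha > eps) | (y < 0 & alpha < C - eps)
    hi <- if (any(up)) max(yg[up]) else -Inf
    lw <- if (any(lo)) min(yg[lo]) else Inf
    # KKT admits any b in [max_{I_up} yg, min_{I_low} yg]; take the midpoint
    b <- (hi + lw) / 2
    if (!is.finite(b)) b <- 0
  }
  objective <- 0.5 * (sum(alpha) - sum(alpha * grad))
  list(alpha = alpha, b = b, objective = objective, iterations = iter)
}

#' Fit a soft-margin support vector machine
#'
#' Solves the Wolfe dual of the soft-margin SVM
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j}
#'   \alpha_i\alpha_j y_i y_j K(x_i, x_j)
#'   \quad\text{s.t.}\quad 0 \le \alpha_i \le C,\ \sum_i \alpha_i y_i = 0}
#' by sequential minimal optimization with deterministic
#' maximal-violating-pair selection. Examples with `alpha > 0` are the
#' support vectors; the bias `b` is the mean over unbounded support vectors
#' (`0 < alpha < C`) of `y_i - sum_j alpha_j y_j K(x_j, x_i)`, falling back
#' to the KKT interval midpoint when none are unbounded. For linear kernels
#' the primal weight vector `w = sum_i alpha_i y_i x_i` is cached.
#'
#' By default features are z-scored with training-set statistics before
#' kernel evaluation (gist entries have heterogeneous scales across
#' orientations); the statistics are stored on the model and re-applied at
#' prediction time, so no information flows from test data into scaling.
#'
#' @param x numeric feature matrix, one row per example.
#' @param y labels in `{+1, -1}` (numeric) or `"normal"`/`"abnormal"`
#'   (mapped via [label_to_class()]). Both classes must be present.
#' @param C box constraint (misclassification penalty), > 0.
#' @param kernel an [svm_kernel()]; default linear.
#' @param scale z-score features with training statistics (default `TRUE`).
#' @param tol SMO stopping tolerance on the KKT violation (default 1e-6).
#' @return an object of class `gist_svm` with components `alpha`, `b`,
#'   `sv_index`, `sv_x`, `sv_y`, `sv_alpha`, `w` (linear only), `kernel`,
#'   `C`, `objective`, `center`, `scaling`.
#' @examples
#' m <- svm_fit(matrix(c(-1, 1)), c(-1, 1), C = 10, scale = FALSE)
#' coef(m)        # b = 0, w = 1
#' predict(m, matrix(c(-3, 0.5)))
#' @export
svm_fit <- function(x, y, C = 1, kernel = svm_kernel("linear"),
                    scale = TRUE, tol = 1e-6) {
  x <- as.matrix(x)
  if (is.character(y) || is.factor(y)) y <- label_to_class(as.character(y))
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be +1/-1 or \"normal\"/\"abnormal\"", call. = FALSE)
  if (nrow(x) != length(y))
    stop("`x` rows and `y` length differ", call. = FALSE)
  if (nrow(x) < 2L || length(unique(y)) < 2L)
    stop("training requires at least two examples and both classes",
         call. = FALSE)
  if (!all(is.finite(x)))
    stop("features must be finite", call. = FALSE)
  if (C <= 0) stop("`C` must be > 0", call. = FALSE)

  if (scale) {
    center <- colMeans(x)
    scaling <- apply(x, 2, stats::sd)
    scaling[!is.finite(scaling) | scaling < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scaling, "/")
  } else {
    center <- rep(0, ncol(x)); scaling <- rep(1, ncol(x))
    xs <- x
  }

  K <- kernel_matrix(kernel, xs)
  sol <- smo_solve(K, y, C, tol = tol)
  sv <- which(sol$alpha > 1e-12 * max(C, 1))
  w <- if (kernel$family == "linear")
    drop(crossprod(xs, sol$alpha * y)) else NULL
  structure(
    list(alpha = sol$alpha, b = sol$b, sv_index = sv,
         sv_x = xs[sv, , drop = FALSE], sv_y = y[sv],
         sv_alpha = sol$alpha[sv], w = w, kernel = kernel, C = C,
         objective = sol$objective, iterations = sol$iterations,
         center = center, scaling = scaling, n_train = nrow(x),
         dim = ncol(x)),
    class = "gist_svm"
  )
}

apply_scaling <- function(object, x) {
  sweep(sweep(x, 2, object$center), 2, object$scaling, "/")
}

#' SVM decision values and class predictions
#'
#' `decision_function()` evaluates
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` over the support vectors (for
#' linear kernels this equals `w . x + b` to rounding). `predict()` returns
#' `sign(f(x))`, with the tie `f(x) = 0` mapped to `+1`.
#'
#' @param model,object a fitted [svm_fit()] model.
#' @param x,newdata feature matrix (or single vector) to score.
#' @param type `"class"` for labels in `{+1, -1}`, `"decision"` for raw
#'   decision values.
#' @param ... unused.
#' @return numeric vector of decision values or class labels.
#' @export
decision_function <- function(model, x) {
  stopifnot(inherits(model, "gist_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$dim)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(x), model$dim), call. = FALSE)
  xs <- apply_scaling(model, x)
  if (length(model$sv_index) == 0L) return(rep(model$b, nrow(x)))
  Kx <- kernel_matrix(model$kernel, xs, model$sv_x)
  drop(Kx %*% (model$sv_alpha * model$sv_y)) + model$b
}

#' @rdname decision_function
#' @export
predict.gist_svm <- function(object, newdata, type = c("class", "decision"),
                             ...) {
  type <- match.arg(type)
  f <- decision_function(object, newdata)
  if (type == "decision") return(f)
  ifelse(f >= 0, 1, -1)
}

#' @export
coef.gist_svm <- function(object, ...) {
  if (is.null(object$w))
    stop("primal coefficients are only defined for the linear kernel",
         call. = FALSE)
  c(b = object$b, object$w)
}

#' @export
print.gist_svm <- function(x, ...) {
  cat(sprintf("<gist_svm> %s kernel, C = %g\n", x$kernel$family, x$C))
  cat(sprintf("  %d support vectors of %d training examples; b = %.6g\n",
              length(x$sv_index), x$n_train, x$b))
  invisible(x)
}

#' @export
summary.gist_svm <- function(object, ...) {
  n_free <- sum(object$sv_alpha < object$C - 1e-12 * max(object$C, 1))
  cat(sprintf("Soft-margin SVM (%s kernel), C = %g\n",
              object$kernel$family, object$C))
  cat(sprintf("  training examples : %d (dim %d)\n",
              object$n_train, object$dim))
  cat(sprintf("  support vectors   : %d (%d unbounded, %d at C)\n",
              length(object$sv_index), n_free,
              length(object$sv_index) - n_free))
  cat(sprintf("  dual objective    : %.8g\n", object$objective))
  cat(sprintf("  bias b            : %.8g\n", object$b))
  if (!is.null(object$w))
    cat(sprintf("  ||w||             : %.8g (geometric margin 2/||w|| = %.8g)\n",
                sqrt(sum(object$w^2)), 2 / sqrt(sum(object$w^2))))
  invisible(object)
}

# Stratified k-fold assignment: within each class, a seeded shuffle then
# round-robin fold labels, so folds are as balanced as the counts allow.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  for (f in seq_len(k)) {
    tr <- y[folds != f]
    if (length(unique(tr)) < 2L)
      stop("cannot form stratified folds with both classes in every training split; reduce k or add data",
           call. = FALSE)
  }
  folds
}

#' Choose the box constraint C by cross-validation
#'
#' Evaluates each candidate C by stratified k-fold cross-validated accuracy
#' (scaling and fitting happen inside each training fold) and returns the
#' candidate with the highest mean accuracy; exact ties break toward the
#' smallest C.
#'
#' @param x,y,kernel,scale as in [svm_fit()].
#' @param grid candidate C values; default `c(0.01, 0.1, 1, 10, 100)`.
#' @param k number of folds, >= 2 (default 5).
#' @param seed integer seed for the fold assignment.
#' @return the chosen C, with the per-candidate mean accuracies attached as
#'   attribute `"cv_accuracy"`.
#' @export
select_C <- function(x, y, grid = c(0.01, 0.1, 1, 10, 100), k = 5L,
                     kernel = svm_kernel("linear"), scale = TRUE, seed = 1L) {
  x <- as.matrix(x)
  if (is.character(y) || is.factor(y)) y <- label_to_class(as.character(y))
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  grid <- sort(grid)
  folds <- stratified_folds(y, k, seed)
  acc <- vapply(grid, function(C) {
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (!any(!tr)) return(NA_real_)
      fit <- svm_fit(x[tr, , drop = FALSE], y[tr], C = C, kernel = kernel,
                     scale = scale)
      accuracy(predict(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  best <- grid[which.max(acc)]   # which.max -> first max -> smallest C on ties
  attr(best, "cv_accuracy") <- stats::setNames(acc, grid)
  best
}
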