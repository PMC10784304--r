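#' Linear soft-margin SVM (hinge loss)
#'
#' Fits `min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w'x_i)` by dual
#' coordinate descent, with the intercept absorbed into an appended
#' constant feature. This is the classifier behind [nested_cv()];
#' deterministic given the R RNG state.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels: a factor with two levels, or a +/-1 vector.
#'   The second factor level is coded +1.
#' @param cost soft-margin cost parameter C (> 0).
#' @param max_epochs maximum coordinate-descent sweeps.
#' @param tol convergence tolerance on the maximal projected gradient.
#' @return Object of class `linear_svm` with elements `w` (weights),
#'   `b` (intercept), `levels`, `cost`.
#' @export
linear_svm <- function(x, y, cost = 1, max_epochs = 200, tol = 1e-3) {
  x <- as.matrix(x)
  if (cost <= 0) stop("cost must be positive")
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    lev <- levels(droplevels(y))
    if (length(lev) != 2) stop("y must have exactly two classes")
    yy <- ifelse(y == lev[2], 1, -1)
  } else {
    lev <- c("-1", "1")
    yy <- sign(y)
    if (any(yy == 0)) stop("y must be +/-1 or a two-level factor")
  }
  xa <- cbind(x, 1)
  fit <- dcd_linear_svm(t(xa), as.numeric(yy), cost,
                        as.integer(max_epochs), tol)
  structure(list(w = fit$w[-length(fit$w)], b = fit$w[length(fit$w)],
                 levels = lev, cost = cost, epochs = fit$epochs),
            class = "linear_svm")
}

#' @param object a `linear_svm` fit.
#' @param newdata feature matrix to predict.
#' @param ... unused.
#' @rdname linear_svm
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  factor(object$levels[(score > 0) + 1L], levels = object$levels)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> C = %g, %d features, %d epochs\n",
              x$cost, length(x$w), x$epochs))
  invisible(x)
}
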