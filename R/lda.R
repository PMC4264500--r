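#' Train a linear discriminant classifier
#'
#' Two-class Fisher LDA with a shared (pooled) covariance:
#' `w = S_pooled^-1 (mu_act - mu_ref)`, with the bias placing the decision
#' boundary at the pooled class midpoint.  Predicts the activity class
#' (label 1) when `w . x + b > 0`.  When the pooled covariance is
#' ill-conditioned or the sample is small relative to the dimension
#' (n < 2d), the covariance is shrunk toward a scaled identity.
#'
#' @param x_ref matrix (samples x features) of reference-class samples.
#' @param x_act matrix of activity-class samples.
#' @param shrinkage shrinkage weight in [0, 1]; `NULL` (default) selects 0
#'   for well-conditioned problems and 0.1 when n < 2d or the condition
#'   number exceeds 1e8.
#' @return An `lda_model`: list with `w`, `b`, class means and the
#'   shrinkage used.
#' @examples
#' m <- train_lda(matrix(rnorm(50)), matrix(rnorm(50) + 2))
#' predict(m, matrix(c(-1, 3), 2))
#' @export
train_lda <- function(x_ref, x_act, shrinkage = NULL) {
  x_ref <- as.matrix(x_ref); x_act <- as.matrix(x_act)
  if (nrow(x_ref) < 2 || nrow(x_act) < 2)
    stopf("need >= 2 samples per class")
  if (!all(is.finite(x_ref)) || !all(is.finite(x_act)))
    stopf("non-finite features")
  d <- ncol(x_ref)
  n <- nrow(x_ref) + nrow(x_act)
  mu_r <- colMeans(x_ref); mu_a <- colMeans(x_act)
  S <- (crossprod(sweep(x_ref, 2, mu_r)) +
        crossprod(sweep(x_act, 2, mu_a))) / (n - 2)
  if (is.null(shrinkage)) {
    kappa_ <- tryCatch(kappa(S, exact = FALSE), error = function(e) Inf)
    shrinkage <- if (n < 2 * d || !is.finite(kappa_) || kappa_ > 1e8) 0.1 else 0
  }
  if (shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(d)
  if (all(S == 0)) stopf("all features constant")
  w <- solve(S, mu_a - mu_r)
  b <- -sum(w * (mu_a + mu_r) / 2)
  structure(list(w = as.numeric(w), b = b, mu_ref = mu_r, mu_act = mu_a,
                 shrinkage = shrinkage,
                 classes = c(reference = 0, activity = 1)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, |w| = %.3g, b = %.3g\n",
              length(x$w), sqrt(sum(x$w^2)), x$b))
  invisible(x)
}

#' @rdname train_lda
#' @param object an `lda_model`.
#' @param newdata matrix (samples x features) or vector of one sample.
#' @param ... unused.
#' @return `predict` returns an integer vector of 0 (reference) / 1
#'   (activity); decision values are attached as the `decision` attribute.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  d <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  structure(as.integer(d > 0), decision = d)
}
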