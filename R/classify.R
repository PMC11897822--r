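# Classifiers on fused vectors.
#
# Two kinds, mirroring the framework's "SVM or a fully connected layer":
#  * "margin": a soft-margin kernel machine (least-squares SVM: kernel
#    ridge on +/-1 targets with an unpenalized bias), linear or RBF kernel,
#    with decision-function scores. Deterministic, and rotation-invariant
#    with the RBF kernel.
#  * "linear": a single linear layer trained by ridge-penalized logistic
#    (softmax with c = 2) loss via IRLS. Exposed with a symmetric
#    (L+Lcv) x 2 weight matrix W and length-2 bias so scores follow
#    u = W'z + bias; this is the classifier the CAM path requires.

as_design <- function(Z) {
  if (inherits(Z, "fused_vector")) Z <- Z$vector
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
  storage.mode(Z) <- "double"
  assert_finite(Z, "design matrix")
  Z
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# median-of-squared-distances bandwidth heuristic
gamma_heuristic <- function(X) {
  n <- nrow(X)
  idx <- if (n > 100) seq(1, n, length.out = 100) else seq_len(n)
  S <- X[round(idx), , drop = FALSE]
  d2 <- as.numeric(stats::dist(S))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m == 0) m <- max(1, ncol(X))
  1 / m
}

fit_lssvm <- function(X, t, lambda, kernel, gamma) {
  n <- nrow(X)
  K <- if (kernel == "rbf") rbf_kernel(X, X, gamma) else tcrossprod(X)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(lambda, n)))
  sol <- solve(A, c(0, t))
  list(b = sol[1], alpha = sol[-1])
}

lssvm_decision <- function(model, Xnew) {
  K <- if (model$kernel == "rbf") rbf_kernel(Xnew, model$X, model$gamma)
       else tcrossprod(Xnew, model$X)
  as.numeric(K %*% model$alpha + model$b)
}

# Ridge-penalized binary logistic regression by IRLS (intercept unpenalized).
fit_logistic_ridge <- function(X, t, lambda = 1e-2, maxit = 100L, tol = 1e-10) {
  p <- ncol(X)
  Xa <- cbind(1, X)
  theta <- numeric(p + 1L)
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xa %*% theta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(Xa, t - mu) - pen %*% theta
    H <- crossprod(Xa * w, Xa) + pen
    step <- tryCatch(solve(H, g), error = function(e)
      stop_illcond("logistic Hessian is singular"))
    theta <- theta + step
    if (max(abs(step)) < tol) break
  }
  list(bias = theta[1], w = theta[-1])
}

#' Train a classifier on fused vectors
#'
#' @param Z N x p matrix of fused vectors (or a `fused_vector` holding one).
#' @param labels length-N vector with two classes.
#' @param kind `"margin"` (soft-margin kernel machine, default) or
#'   `"linear"` (single linear layer by regularized logistic loss; required
#'   by the CAM path).
#' @param kernel kernel for the margin kind: `"rbf"` (default) or
#'   `"linear"`.
#' @param lambda regularization strength; for the margin kind, `NULL`
#'   selects from `tune_grid` by internal stratified cross-validation on the
#'   training data only.
#' @param tune_grid candidate lambdas for the margin kind.
#' @param tune_seed seed for the internal tuning folds (deterministic).
#' @return object of class `fsda_classifier`; for the linear kind it carries
#'   `weights` (p x 2 matrix `W`), `bias` (length 2) and `classes`.
#' @export
train_classifier <- function(Z, labels, kind = c("margin", "linear"),
                             kernel = c("rbf", "linear"), lambda = NULL,
                             tune_grid = c(0.01, 0.1, 1), tune_seed = 0L) {
  kind <- match.arg(kind)
  kernel <- match.arg(kernel)
  X <- as_design(Z)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stop_validation("training data contains a single class")
  if (length(classes) > 2L)
    stop_validation("binary classification only")
  y01 <- as.numeric(as.character(labels) == classes[2])
  if (min(sum(y01), sum(1 - y01)) < 2L)
    stop_validation("each class needs >= 2 training samples")

  if (kind == "linear") {
    fit <- fit_logistic_ridge(X, y01, lambda = lambda %||% 1e-2)
    W <- cbind(-fit$w, fit$w)
    colnames(W) <- classes
    return(structure(list(kind = "linear", weights = W,
                          bias = c(-fit$bias, fit$bias), classes = classes),
                     class = "fsda_classifier"))
  }

  gamma <- if (kernel == "rbf") gamma_heuristic(X) else NA_real_
  if (is.null(lambda)) {
    folds <- make_stratified_folds(y01, k = min(3L, min(sum(y01), sum(1 - y01))),
                                   seed = tune_seed)
    acc <- vapply(tune_grid, function(lam) {
      mean(vapply(seq_along(folds), function(f) {
        tr <- setdiff(seq_len(nrow(X)), folds[[f]])
        te <- folds[[f]]
        if (length(unique(y01[tr])) < 2L) return(NA_real_)
        m <- fit_lssvm(X[tr, , drop = FALSE], 2 * y01[tr] - 1, lam, kernel, gamma)
        m <- c(m, list(X = X[tr, , drop = FALSE], kernel = kernel, gamma = gamma))
        pred <- lssvm_decision(m, X[te, , drop = FALSE]) > 0
        mean(pred == (y01[te] == 1))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    lambda <- tune_grid[which.max(acc)]
  }
  m <- fit_lssvm(X, 2 * y01 - 1, lambda, kernel, gamma)
  structure(list(kind = "margin", alpha = m$alpha, b = m$b, X = X,
                 kernel = kernel, gamma = gamma, lambda = lambda,
                 classes = classes),
            class = "fsda_classifier")
}

#' Per-class scores and predicted labels
#'
#' For the linear kind returns `u = W'z + bias` per sample; for the margin
#' kind the decision-function value `f` is returned as the score pair
#' `(-f, f)`. The predicted class is the index of the largest component,
#' ties resolved toward the lower index.
#'
#' @param classifier an `fsda_classifier`.
#' @param Z vector, matrix or `fused_vector` of inputs.
#' @return list with `scores` (N x 2 matrix, columns named by class),
#'   `predicted` (class labels) and `predicted_index`.
#' @export
predict_scores <- function(classifier, Z) {
  stopifnot(inherits(classifier, "fsda_classifier"))
  X <- as_design(Z)
  if (classifier$kind == "linear") {
    if (ncol(X) != nrow(classifier$weights))
      stop_dimension("input width does not match classifier weights")
    u <- sweep(X %*% classifier$weights, 2L, classifier$bias, "+")
  } else {
    if (ncol(X) != ncol(classifier$X))
      stop_dimension("input width does not match training data")
    f <- lssvm_decision(classifier, X)
    u <- cbind(-f, f)
  }
  colnames(u) <- classifier$classes
  idx <- apply(u, 1L, which.max)   # which.max: ties -> lower index
  list(scores = u, predicted = classifier$classes[idx], predicted_index = idx)
}
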