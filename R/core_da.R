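# Recursive Foley-Sammon discriminant directions.
#
# For binary classes the between-class scatter S_B = s_b s_b' has rank one,
# so classical Fisher LDA yields a single direction. The Foley-Sammon
# recursion extracts an ordered set d_1, d_2, ... of unit vectors, each
# maximizing the Fisher criterion R(d) = (s_b'd)^2 / (d'S_W d) subject to
# orthogonality with all earlier directions:
#
#   d_1 = a_1 S_W^{-1} s_b
#   d_n = a_n S_W^{-1} { s_b - [d_1 ... d_{n-1}] S_{n-1}^{-1} (1/a_1, 0, ..., 0)' }
#
# with S_{n-1}[i, j] = d_i' S_W^{-1} d_j and a_n the unit-norm normalizer.
# All "inverse" applications are Cholesky solves of the ridge-regularized
# within-class scatter; the regularization is essential in the M >= N regime
# the package targets, where the raw S_W is singular.

#' Class statistics for binary discriminant analysis
#'
#' Computes class means, the between-class direction `s_b = mean1 - mean2`,
#' per-class scatters and the combined within-class scatter
#' `S_W = beta * S_W1 + (1 - beta) * S_W2` with
#' `beta = (N2 - 1) / (N1 + N2 - 2)`. Each per-class scatter `S_Wj` is the
#' unbiased sample covariance of class j (divisor `Nj - 1`).
#'
#' `within_mode = "as_printed"` uses the cross-weighted combination above
#' (the weight on class 1's scatter comes from class 2's count);
#' `within_mode = "pooled"` uses the classical pooled covariance
#' `((N1-1) S_W1 + (N2-1) S_W2) / (N1 + N2 - 2)`. The two coincide when
#' `N1 == N2`.
#'
#' @param data a [labelled_features] object with >= 2 samples per class.
#' @param within_mode `"as_printed"` (default) or `"pooled"`.
#' @return an object of class `class_statistics`: `overall_mean`,
#'   `class_means` (2 x M), `between_direction`, `within_scatter`,
#'   `per_class_scatters`, `beta`, `class_counts`, `within_mode`.
#' @seealso [fit_basis()], [fisher_criterion()]
#' @export
compute_class_statistics <- function(data,
                                     within_mode = c("as_printed", "pooled")) {
  stopifnot(inherits(data, "labelled_features"))
  within_mode <- match.arg(within_mode)
  n <- data$class_counts
  if (any(n < 2L))
    stop_degenerate("each class needs >= 2 samples to define its scatter")
  X1 <- data$matrix[class_rows(data, 1), , drop = FALSE]
  X2 <- data$matrix[class_rows(data, 2), , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  S1 <- stats::cov(X1)
  S2 <- stats::cov(X2)
  beta <- (n[["N2"]] - 1) / (n[["N1"]] + n[["N2"]] - 2)
  SW <- switch(within_mode,
    as_printed = beta * S1 + (1 - beta) * S2,
    pooled = ((n[["N1"]] - 1) * S1 + (n[["N2"]] - 1) * S2) /
             (n[["N1"]] + n[["N2"]] - 2))
  new_class_statistics(
    between_direction = m1 - m2, within_scatter = SW,
    overall_mean = colMeans(data$matrix),
    class_means = rbind(m1, m2), per_class_scatters = list(S1, S2),
    beta = beta, class_counts = n, within_mode = within_mode,
    label_order = data$label_order)
}

#' Construct class statistics directly from scatter components
#'
#' Low-level constructor used when the between-class direction and
#' within-class scatter are specified analytically (synthetic instances,
#' oracles) rather than estimated from data.
#'
#' @param between_direction length-M vector `s_b`.
#' @param within_scatter symmetric positive semidefinite M x M matrix `S_W`.
#' @param ... optional fields (`overall_mean`, `class_means`,
#'   `per_class_scatters`, `beta`, `class_counts`, `within_mode`,
#'   `label_order`).
#' @return a `class_statistics` object.
#' @export
as_class_statistics <- function(between_direction, within_scatter, ...) {
  new_class_statistics(between_direction = between_direction,
                       within_scatter = within_scatter, ...)
}

new_class_statistics <- function(between_direction, within_scatter,
                                 overall_mean = NULL, class_means = NULL,
                                 per_class_scatters = NULL, beta = NA_real_,
                                 class_counts = NULL, within_mode = NA_character_,
                                 label_order = NULL) {
  between_direction <- as.numeric(between_direction)
  within_scatter <- as.matrix(within_scatter)
  assert_finite(between_direction, "between_direction")
  assert_finite(within_scatter, "within_scatter")
  M <- length(between_direction)
  if (!all(dim(within_scatter) == c(M, M)))
    stop_dimension("within_scatter must be M x M with M = length(between_direction)")
  if (max(abs(within_scatter - t(within_scatter))) > 1e-8 * (1 + max(abs(within_scatter))))
    stop_validation("within_scatter must be symmetric")
  structure(
    list(between_direction = between_direction, within_scatter = within_scatter,
         overall_mean = overall_mean, class_means = class_means,
         per_class_scatters = per_class_scatters, beta = beta,
         class_counts = class_counts, within_mode = within_mode,
         label_order = label_order),
    class = "class_statistics")
}

#' Between-class scatter matrix
#'
#' Materializes the rank-1 matrix `s_b s_b'`. Kept out of the statistics
#' object on purpose: every computation in the package uses `s_b` directly.
#' @param stats a `class_statistics` object.
#' @return M x M matrix.
#' @export
between_scatter <- function(stats) {
  stopifnot(inherits(stats, "class_statistics"))
  tcrossprod(stats$between_direction)
}

# Default ridge: 1e-6 * trace(S_W)/M, i.e. proportional to the mean feature
# variance, so the regularized scatter is invertible in the M >= N regime.
default_ridge <- function(SW) {
  1e-6 * sum(diag(SW)) / ncol(SW)
}

regularized_chol <- function(stats, ridge) {
  SW <- stats$within_scatter
  if (is.null(ridge)) ridge <- default_ridge(SW)
  if (ridge < 0) stop_validation("ridge must be >= 0")
  if (ridge > 0) SW <- SW + diag(ridge, ncol(SW))
  R <- tryCatch(chol(SW), error = function(e)
    stop_illcond("within-class scatter (after ridge) is not positive definite"))
  list(R = R, ridge = ridge)
}

#' Fisher criterion of a projection direction
#'
#' `R(d) = (d' S_B d) / (d' S_W d) = (s_b' d)^2 / (d' S_W d)`, a Rayleigh
#' quotient: invariant to rescaling of `d`.
#'
#' @param d length-M direction, nonzero.
#' @param stats a `class_statistics` object.
#' @param ridge nonnegative ridge added to `S_W`'s diagonal (default 0).
#' @return scalar criterion value.
#' @export
fisher_criterion <- function(d, stats, ridge = 0) {
  stopifnot(inherits(stats, "class_statistics"))
  d <- as.numeric(d)
  if (length(d) != length(stats$between_direction))
    stop_dimension("direction length must match feature dimension")
  assert_finite(d, "direction")
  nd2 <- sum(d^2)
  if (nd2 == 0) stop_validation("direction must be nonzero")
  SW <- stats$within_scatter
  denom <- sum(d * (SW %*% d)) + ridge * nd2
  tol <- .Machine$double.eps * nd2 * max(1, sum(diag(SW)))
  if (denom <= tol)
    stop_illcond("d' S_W d is below tolerance; criterion undefined")
  (sum(stats$between_direction * d))^2 / denom
}

#' First Foley-Sammon discriminant direction
#'
#' `d1 = alpha1 * S_W^{-1} s_b`, the classical Fisher LDA direction,
#' normalized to unit length with sign fixed so `s_b' d1 >= 0`.
#'
#' @inheritParams fisher_criterion
#' @param ridge ridge for `S_W` (default `NULL` = `1e-6 * trace(S_W)/M`).
#' @return list with `direction` (unit vector) and `alpha`
#'   (`1 / ||S_W^{-1} s_b||`).
#' @export
first_direction <- function(stats, ridge = NULL) {
  stopifnot(inherits(stats, "class_statistics"))
  s_b <- stats$between_direction
  if (sqrt(sum(s_b^2)) == 0)
    stop_nodirection("class means coincide (s_b = 0): no discriminant direction")
  rc <- regularized_chol(stats, ridge)
  u <- chol_solve(rc$R, s_b)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop_nodirection("S_W^{-1} s_b vanished")
  list(direction = as.numeric(u / nu), alpha = 1 / nu)
}

#' Next Foley-Sammon discriminant direction
#'
#' Given `n - 1` previously fitted directions, returns the n-th direction
#' maximizing the Fisher criterion in their orthogonal complement, via the
#' recursion with Gram system `S_{n-1}[i, j] = d_i' S_W^{-1} d_j`. When the
#' braced correction vector vanishes the discriminative subspace is
#' exhausted and `exhausted = TRUE` is returned instead of a noise
#' direction.
#'
#' @inheritParams first_direction
#' @param previous a [discriminant_basis] holding `d_1 ... d_{n-1}`.
#' @return list with `direction`, `alpha`, `exhausted` (logical) and `gram`
#'   (the `S_{n-1}` matrix used).
#' @export
next_direction <- function(stats, previous, ridge = NULL) {
  stopifnot(inherits(stats, "class_statistics"),
            inherits(previous, "discriminant_basis"))
  if (is.null(ridge))
    ridge <- if (is.finite(previous$ridge %||% NA_real_)) previous$ridge else NULL
  rc <- regularized_chol(stats, ridge)
  next_direction_chol(stats, previous$projection, previous$alphas[1], rc$R)
}

# Core recursion step given the Cholesky factor of the regularized S_W.
# P is the (n-1) x M matrix of previous directions (rows).
next_direction_chol <- function(stats, P, alpha1, R) {
  s_b <- stats$between_direction
  D <- t(P)                                   # M x (n-1)
  SwinvD <- chol_solve(R, D)
  gram <- crossprod(D, SwinvD)                # S_{n-1}
  rhs <- c(1 / alpha1, rep(0, ncol(D) - 1L))
  coef <- tryCatch(solve(gram, rhs), error = function(e)
    stop_illcond("Gram system S_{n-1} is singular"))
  braced <- s_b - as.numeric(D %*% coef)
  if (sqrt(sum(braced^2)) < 1e-10 * sqrt(sum(s_b^2)))
    return(list(direction = NULL, alpha = NA_real_, exhausted = TRUE,
                gram = gram))
  u <- chol_solve(R, braced)
  nu <- sqrt(sum(u^2))
  if (nu < 1e-14)
    return(list(direction = NULL, alpha = NA_real_, exhausted = TRUE,
                gram = gram))
  d <- as.numeric(u) / nu
  # remove accumulated round-off against previous directions (a no-op in
  # exact arithmetic: the recursion is orthogonal by construction)
  d <- d - as.numeric(D %*% crossprod(D, d))
  d <- d / sqrt(sum(d^2))
  # deterministic sign: s_b' d >= 0, ties broken by first nonzero coordinate
  pr <- sum(s_b * d)
  if (abs(pr) > 1e-12) {
    if (pr < 0) d <- -d
  } else {
    nz <- which(abs(d) > 1e-12)[1]
    if (!is.na(nz) && d[nz] < 0) d <- -d
  }
  list(direction = d, alpha = 1 / nu, exhausted = FALSE, gram = gram)
}

#' Construct a discriminant basis from an explicit projection matrix
#'
#' Low-level constructor; rows of `P` must be orthonormal. Used internally
#' by [fit_basis()] and directly when a fixed projection (e.g. identity) is
#' wanted.
#'
#' @param P L x M projection matrix with orthonormal rows.
#' @param alphas,criterion_values optional per-direction normalizers and
#'   Fisher criterion values.
#' @param gram optional Gram system matrix retained for audit.
#' @param within_mode,ridge,label_order optional fit metadata.
#' @return object of class `discriminant_basis`.
#' @export
discriminant_basis <- function(P, alphas = NULL, criterion_values = NULL,
                               gram = NULL, within_mode = NA_character_,
                               ridge = NA_real_, label_order = NULL) {
  P <- as.matrix(P)
  assert_finite(P, "projection matrix")
  G <- tcrossprod(P)
  if (max(abs(G - diag(nrow(P)))) > 1e-8)
    stop_validation("rows of P must be orthonormal (P P' = I)")
  structure(
    list(projection = P, L = nrow(P), M = ncol(P),
         alphas = alphas %||% rep(NA_real_, nrow(P)),
         criterion_values = criterion_values %||% rep(NA_real_, nrow(P)),
         gram = gram, within_mode = within_mode, ridge = ridge,
         label_order = label_order),
    class = "discriminant_basis")
}

#' @export
print.discriminant_basis <- function(x, ...) {
  cat(sprintf("<discriminant_basis> L = %d directions in M = %d dimensions (ridge = %g)\n",
              x$L, x$M, x$ridge))
  if (!all(is.na(x$criterion_values)))
    cat("  Fisher criterion: ",
        paste(signif(x$criterion_values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit an ordered Foley-Sammon discriminant basis
#'
#' Iterates [first_direction()] then [next_direction()] up to `L` directions,
#' truncating with a warning if the discriminative subspace is exhausted
#' first. The default `L = 10` matches the reduction size used throughout
#' the experiments this package reproduces.
#'
#' @param x a [labelled_features] object or a `class_statistics` object.
#' @param L number of directions requested (>= 1).
#' @param ridge ridge added to `S_W` before each solve; `NULL` (default)
#'   means `1e-6 * trace(S_W)/M`.
#' @param ... passed to methods.
#' @return a [discriminant_basis] with projection `P = (d1, ..., dL)'`.
#' @examples
#' lf <- labelled_features(matrix(rnorm(200), 50, 4), rep(1:2, 25))
#' b <- fit_basis(lf, L = 3)
#' tcrossprod(b$projection)  # identity: rows orthonormal
#' @export
fit_basis <- function(x, L = 10L, ...) UseMethod("fit_basis")

#' @rdname fit_basis
#' @inheritParams compute_class_statistics
#' @export
fit_basis.labelled_features <- function(x, L = 10L,
                                        within_mode = c("as_printed", "pooled"),
                                        ridge = NULL, ...) {
  stats <- compute_class_statistics(x, match.arg(within_mode))
  fit_basis(stats, L = L, ridge = ridge)
}

#' @rdname fit_basis
#' @export
fit_basis.class_statistics <- function(x, L = 10L, ridge = NULL, ...) {
  L <- as.integer(L)
  if (L < 1L) stop_validation("L must be >= 1")
  if (L > length(x$between_direction))
    stop_validation("L cannot exceed the feature dimension M")
  rc <- regularized_chol(x, ridge)
  f1 <- {
    s_b <- x$between_direction
    if (sqrt(sum(s_b^2)) == 0)
      stop_nodirection("class means coincide (s_b = 0): no discriminant direction")
    u <- chol_solve(rc$R, s_b)
    nu <- sqrt(sum(u^2))
    list(direction = as.numeric(u / nu), alpha = 1 / nu)
  }
  dirs <- matrix(f1$direction, nrow = 1L)
  alphas <- f1$alpha
  gram <- NULL
  n <- 2L
  while (n <= L) {
    step <- next_direction_chol(x, dirs, alphas[1], rc$R)
    gram <- step$gram
    if (step$exhausted) {
      warning(sprintf(
        "discriminative subspace exhausted after %d direction(s); requested L = %d",
        n - 1L, L), call. = FALSE)
      break
    }
    dirs <- rbind(dirs, step$direction)
    alphas <- c(alphas, step$alpha)
    n <- n + 1L
  }
  crit <- apply(dirs, 1L, fisher_criterion, stats = x, ridge = rc$ridge)
  # full Gram of the fitted directions under S_W^{-1}, retained for audit
  SwinvD <- chol_solve(rc$R, t(dirs))
  gram_full <- crossprod(t(dirs), SwinvD)
  discriminant_basis(dirs, alphas = alphas, criterion_values = crit,
                     gram = gram_full, within_mode = x$within_mode,
                     ridge = rc$ridge, label_order = x$label_order)
}

#' Project features onto a discriminant basis
#'
#' Computes the reduced representation `P y` for a single length-M vector or
#' row-wise for an N x M matrix (or [labelled_features]).
#'
#' @param basis a [discriminant_basis].
#' @param y length-M vector, N x M matrix, or [labelled_features].
#' @return length-L vector or N x L matrix of reduced features.
#' @export
project <- function(basis, y) {
  stopifnot(inherits(basis, "discriminant_basis"))
  if (inherits(y, "labelled_features")) y <- y$matrix
  if (is.matrix(y)) {
    if (ncol(y) != basis$M)
      stop_dimension(sprintf("expected %d columns, got %d", basis$M, ncol(y)))
    assert_finite(y, "features")
    return(y %*% t(basis$projection))
  }
  y <- as.numeric(y)
  if (length(y) != basis$M)
    stop_dimension(sprintf("expected length %d, got %d", basis$M, length(y)))
  assert_finite(y, "features")
  as.numeric(basis$projection %*% y)
}

#' Persist / load a fitted discriminant basis
#'
#' Stores the projection, normalizers, criterion values and fit metadata in
#' a binary array container (RDS).
#' @param basis a [discriminant_basis].
#' @param path file path.
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "discriminant_basis"))
  saveRDS(unclass(basis), path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  x <- readRDS(path)
  discriminant_basis(x$projection, alphas = x$alphas,
                     criterion_values = x$criterion_values, gram = x$gram,
                     within_mode = x$within_mode, ridge = x$ridge,
                     label_order = x$label_order)
}
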