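# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written from first principles (textbook
# formulas, dense eigendecompositions, explicit loops) so it never shares a
# code path with the implementation it checks.

# random symmetric positive definite matrix
random_spd <- function(M, jitter = 0.5) {
  A <- matrix(rnorm(M * M), M)
  crossprod(A) + diag(M) * jitter
}

# random discriminant-analysis instance built directly from scatters
random_da_instance <- function(M) {
  list(stats = as_class_statistics(rnorm(M), random_spd(M)), M = M)
}

# leading generalized eigenvector of (S_B, S_W) with S_B = s_b s_b',
# solved as an ordinary dense eigenproblem of S_W^{-1} S_B
oracle_gen_eigvec <- function(s_b, SW) {
  ev <- eigen(solve(SW, tcrossprod(s_b)))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v <- v / sqrt(sum(v^2))
  if (sum(v * s_b) < 0) v <- -v
  v
}

# second direction by the closed form: explicit matrix powers of S_W^{-1}
oracle_d2_closed_form <- function(s_b, SW) {
  Si <- solve(SW)
  Si2 <- Si %*% Si
  Si3 <- Si2 %*% Si
  num <- as.numeric(t(s_b) %*% Si2 %*% s_b)
  den <- as.numeric(t(s_b) %*% Si3 %*% s_b)
  d2 <- as.numeric((Si - (num / den) * Si2) %*% s_b)
  d2 <- d2 / sqrt(sum(d2^2))
  if (sum(d2 * s_b) < 0) d2 <- -d2
  d2
}

# Fisher criterion by direct arithmetic (no shared code with the package)
oracle_fisher <- function(d, s_b, SW) {
  (sum(s_b * d))^2 / as.numeric(t(d) %*% SW %*% d)
}

# best criterion among n random unit vectors confined to the orthogonal
# complement of the columns of D (may be NULL)
oracle_best_random <- function(s_b, SW, D = NULL, n = 1e4) {
  M <- length(s_b)
  V <- matrix(rnorm(n * M), ncol = M)
  if (!is.null(D)) V <- V - V %*% D %*% t(D)
  keep <- rowSums(V^2) > 1e-12
  V <- V[keep, , drop = FALSE]
  max((V %*% s_b)^2 / rowSums((V %*% SW) * V))
}

# textbook CAM: explicit loop over channels, weighted sum of channel maps
oracle_standard_cam <- function(tensor, w) {
  d <- dim(tensor)
  out <- matrix(0, d[2], d[3])
  for (m in seq_len(d[1])) out <- out + w[m] * tensor[m, , ]
  out
}

synth_labels_of <- function(cfg) rep(1:2, each = cfg$n_per_class)

# class-conditional Gaussian features without going through synth_config
toy_features <- function(n_per_class, M, delta, seed = 1) {
  fsdacam:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * M), n_per_class),
               matrix(rnorm(n_per_class * M), n_per_class))
    X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + delta
    labelled_features(X, rep(1:2, each = n_per_class))
  })
}
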