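# Discriminant core: class statistics, Fisher criterion, recursion.

test_that("class statistics match hand-computed scatters", {
  # Class 1 = {(0,0),(2,0)}, class 2 = {(1,1),(1,3)}
  lf <- labelled_features(rbind(c(0, 0), c(2, 0), c(1, 1), c(1, 3)),
                          c(1, 1, 2, 2))
  st <- compute_class_statistics(lf)
  expect_equal(st$between_direction, c(0, -2))
  expect_equal(unname(st$per_class_scatters[[1]]),
               rbind(c(2, 0), c(0, 0)))
  expect_equal(unname(st$per_class_scatters[[2]]),
               rbind(c(0, 0), c(0, 2)))
  expect_equal(st$beta, 0.5)
  expect_equal(unname(st$within_scatter), diag(2))
  # cross-check against a direct textbook covariance computation
  expect_equal(unname(st$per_class_scatters[[1]]),
               unname(cov(rbind(c(0, 0), c(2, 0)))))
})

test_that("as_printed equals pooled when N1 == N2, differs otherwise", {
  set.seed(11)
  lf <- toy_features(10, 4, delta = 1, seed = 11)
  a <- compute_class_statistics(lf, "as_printed")
  p <- compute_class_statistics(lf, "pooled")
  expect_equal(a$beta, 0.5)
  expect_equal(a$within_scatter, p$within_scatter)

  X <- rbind(matrix(rnorm(12), 3), matrix(rnorm(28), 7))
  lf2 <- labelled_features(X, rep(1:2, c(3, 7)))
  a2 <- compute_class_statistics(lf2, "as_printed")
  p2 <- compute_class_statistics(lf2, "pooled")
  expect_equal(a2$beta, 6 / 8)
  # cross-weighting: class-2 count weights class-1 scatter
  expect_equal(a2$within_scatter,
               6 / 8 * a2$per_class_scatters[[1]] +
                 2 / 8 * a2$per_class_scatters[[2]])
  expect_gt(max(abs(a2$within_scatter - p2$within_scatter)), 1e-8)
})

test_that("degenerate inputs raise typed errors", {
  lf <- labelled_features(matrix(rnorm(6), 3), c(1, 2, 2))
  expect_error(compute_class_statistics(lf),
               class = "fsdacam_degenerate_class_error")
  expect_error(labelled_features(matrix(c(1, NA), 2), c(1, 2)),
               class = "fsdacam_validation_error")
  expect_error(labelled_features(matrix(rnorm(4), 2), c(1, 1)),
               class = "fsdacam_validation_error")
  # identical classes: s_b = 0 -> no direction
  X <- rbind(c(1, 2), c(3, 4), c(1, 2), c(3, 4))
  st <- compute_class_statistics(labelled_features(X, c(1, 1, 2, 2)))
  expect_equal(st$between_direction, c(0, 0))
  expect_error(first_direction(st), class = "fsdacam_no_direction_error")
})

test_that("Fisher criterion: value, scale invariance, orthogonal null", {
  st <- as_class_statistics(c(3, 4), diag(2))
  expect_equal(fisher_criterion(c(3, 4), st), 25)
  expect_equal(fisher_criterion(c(-4, 3), st), 0)   # d perpendicular to s_b
  set.seed(21)
  for (i in 1:10) {
    M <- sample(2:8, 1)
    inst <- random_da_instance(M)
    d <- rnorm(M)
    r1 <- fisher_criterion(d, inst$stats)
    expect_equal(fisher_criterion(2 * d, inst$stats), r1)
    expect_equal(fisher_criterion(-0.3 * d, inst$stats), r1)
    expect_equal(r1, oracle_fisher(d, inst$stats$between_direction,
                                   inst$stats$within_scatter))
  }
  expect_error(fisher_criterion(c(0, 0), st),
               class = "fsdacam_validation_error")
})

test_that("first direction: identity scatter, eigen oracle, maximality", {
  st <- as_class_statistics(c(0, 0, 0, 5), diag(4))
  f <- first_direction(st, ridge = 0)
  expect_equal(f$direction, c(0, 0, 0, 1))
  expect_equal(f$alpha, 1 / 5)

  set.seed(31)
  for (i in 1:10) {
    M <- 8
    inst <- random_da_instance(M)
    s_b <- inst$stats$between_direction
    SW <- inst$stats$within_scatter
    f <- first_direction(inst$stats, ridge = 0)
    expect_equal(f$direction, oracle_gen_eigvec(s_b, SW), tolerance = 1e-6)
    expect_gte(fisher_criterion(f$direction, inst$stats) + 1e-12,
               oracle_best_random(s_b, SW, n = 1e3))
  }
})

test_that("recursion equals the closed-form second direction", {
  set.seed(41)
  for (i in 1:10) {
    inst <- random_da_instance(6)
    b <- fit_basis(inst$stats, L = 2, ridge = 0)
    d2o <- oracle_d2_closed_form(inst$stats$between_direction,
                                 inst$stats$within_scatter)
    expect_lt(max(abs(b$projection[2, ] - d2o)), 1e-8)
  }
})

test_that("identity within-scatter exhausts the subspace after d1", {
  st <- as_class_statistics(c(1, 2, 2), diag(3))
  f <- first_direction(st, ridge = 0)
  expect_equal(f$direction, c(1, 2, 2) / 3)
  prev <- discriminant_basis(matrix(f$direction, 1), alphas = f$alpha)
  nd <- next_direction(st, prev, ridge = 0)
  expect_true(nd$exhausted)
  expect_warning(b <- fit_basis(st, L = 3, ridge = 0), "exhausted")
  expect_equal(b$L, 1L)
})

test_that("fitted bases are orthonormal and permutation invariant", {
  set.seed(51)
  lf <- toy_features(25, 20, delta = 2, seed = 51)
  b <- fit_basis(lf, L = 10)
  expect_equal(b$L, 10L)
  expect_lt(max(abs(tcrossprod(b$projection) - diag(10))), 1e-8)
  expect_lt(max(abs(sqrt(rowSums(b$projection^2)) - 1)), 1e-8)

  perm <- sample(nrow(lf$matrix))
  lf2 <- labelled_features(lf$matrix[perm, ], lf$labels[perm])
  b2 <- fit_basis(lf2, L = 10)
  expect_equal(b$projection, b2$projection, tolerance = 1e-6)
})

test_that("L = 1 reduces to the classical Fisher LDA direction", {
  lf <- toy_features(20, 5, delta = 3, seed = 61)
  st <- compute_class_statistics(lf)
  b <- fit_basis(lf, L = 1)
  f <- first_direction(st)
  expect_equal(as.numeric(b$projection), f$direction)
  expect_equal(b$alphas, f$alpha)
})

test_that("projection is linear, batch-consistent, dimension-checked", {
  set.seed(71)
  b <- fit_basis(toy_features(15, 8, delta = 2, seed = 71), L = 3)
  y1 <- rnorm(8); y2 <- rnorm(8)
  expect_equal(project(b, 2 * y1 + 3 * y2),
               2 * project(b, y1) + 3 * project(b, y2))
  expect_equal(project(b, numeric(8)), numeric(3))
  Y <- rbind(y1, y2)
  batch <- project(b, Y)
  expect_identical(dim(batch), c(2L, 3L))
  expect_equal(unname(batch[1, ]), project(b, y1))
  expect_equal(unname(batch[2, ]), project(b, y2))
  expect_error(project(b, rnorm(7)), class = "fsdacam_dimension_error")
  # single-row projection: P = e_k' picks coordinate k
  bk <- discriminant_basis(matrix(c(0, 1, 0), 1))
  expect_equal(project(bk, c(5, 7, 9)), 7)
})

test_that("between_scatter materializes the rank-1 outer product", {
  st <- as_class_statistics(c(1, -2), diag(2))
  expect_equal(between_scatter(st), rbind(c(1, -2), c(-2, 4)))
  expect_equal(qr(between_scatter(st))$rank, 1L)
})

test_that("basis round-trips through its array container", {
  b <- fit_basis(toy_features(10, 6, delta = 2, seed = 81), L = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  write_basis(b, path)
  b2 <- read_basis(path)
  expect_equal(b$projection, b2$projection)
  expect_equal(b$alphas, b2$alphas)
  expect_equal(b$ridge, b2$ridge)
})
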