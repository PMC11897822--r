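# Classifiers and the cross-validated comparison protocol.

test_that("separable toy data is fit perfectly by both classifier kinds", {
  Z <- rbind(c(-2, 0), c(-2, 1), c(2, 0), c(2, 1))
  y <- c("a", "a", "b", "b")
  for (kind in c("margin", "linear")) {
    clf <- train_classifier(Z, y, kind = kind)
    expect_equal(predict_scores(clf, Z)$predicted, y)
  }
  expect_error(train_classifier(Z, rep("a", 4)),
               class = "fsdacam_validation_error")
})

test_that("linear classifier weight sign follows the class ordering", {
  set.seed(2)
  x <- matrix(c(rnorm(50, -1, 0.3), rnorm(50, 1, 0.3)), ncol = 1)
  y <- rep(1:2, each = 50)
  clf <- train_classifier(x, y, kind = "linear")
  # column for class "2" (means at +1) must weight x positively
  expect_gt(clf$weights[1, "2"], 0)
  expect_lt(clf$weights[1, "1"], 0)
  expect_equal(unname(clf$weights[, "1"]), unname(-clf$weights[, "2"]))
})

test_that("predict_scores obeys u = W'z + bias, tie rule, batch equality", {
  clf <- structure(list(kind = "linear", weights = diag(2),
                        bias = c(0, 0), classes = c("c1", "c2")),
                   class = "fsda_classifier")
  out <- predict_scores(clf, c(3, 1))
  expect_equal(unname(out$scores[1, ]), c(3, 1))
  expect_equal(out$predicted, "c1")
  # equal components -> lower index wins
  expect_equal(predict_scores(clf, c(2, 2))$predicted, "c1")
  # batch equals per-sample
  Z <- matrix(rnorm(10), 5, 2)
  batch <- predict_scores(clf, Z)$scores
  single <- t(sapply(seq_len(5), function(i)
    predict_scores(clf, Z[i, ])$scores[1, ]))
  expect_equal(unname(batch), unname(single))
  expect_error(predict_scores(clf, c(1, 2, 3)),
               class = "fsdacam_dimension_error")
})

test_that("label-independent features give chance-level CV AUC", {
  set.seed(3)
  lf <- labelled_features(matrix(rnorm(200 * 5), 200), rep(1:2, 100))
  r <- cross_validate(lf, arms = "original", folds = 5, seed = 3)
  expect_gt(r$summary$auc_mean, 0.4)
  expect_lt(r$summary$auc_mean, 0.6)
})

test_that("stratified folds are balanced, exhaustive and seed-determined", {
  y <- rep(c("a", "b"), c(40, 60))
  f1 <- make_stratified_folds(y, 5, seed = 9)
  f2 <- make_stratified_folds(y, 5, seed = 9)
  expect_identical(f1, f2)
  expect_setequal(unlist(f1), seq_along(y))
  for (f in f1) {
    expect_equal(sum(y[f] == "a"), 8)
    expect_equal(sum(y[f] == "b"), 12)
  }
  f3 <- make_stratified_folds(y, 5, seed = 10)
  expect_false(identical(f1, f3))
})

test_that("well-separated Gaussians reach near-perfect DA+CV accuracy", {
  cfg <- synth_config(n_per_class = 40, M = 64, informative_dims = 1:4,
                      delta = 5, clinical_effect = 0.5, seed = 13)
  lf <- gen_features(cfg)
  cl <- gen_clinical(cfg, lf$labels)
  r <- cross_validate(lf, clinical = cl$table, schema = cl$schema,
                      arms = c("DA", "DA+CV"), folds = 5, L = 5, seed = 13)
  expect_gte(r$summary$acc_mean[r$summary$arm == "DA+CV"], 0.95)
})

test_that("report bookkeeping: mean/sd recomputable, config fingerprint", {
  lf <- toy_features(20, 10, delta = 2, seed = 17)
  r <- cross_validate(lf, arms = c("original", "DA"), folds = 4, L = 3,
                      seed = 17)
  for (arm in r$summary$arm) {
    d <- r$folds[r$folds$arm == arm, ]
    expect_equal(r$summary$acc_mean[r$summary$arm == arm], mean(d$acc))
    expect_equal(r$summary$acc_sd[r$summary$arm == arm], sd(d$acc))
    expect_equal(r$summary$auc_sd[r$summary$arm == arm], sd(d$auc))
  }
  expect_equal(r$config$seed, 17)
  expect_equal(r$config$L, 3)
  expect_equal(r$config$positive, "2")
  # identical seed + inputs -> identical report
  r2 <- cross_validate(lf, arms = c("original", "DA"), folds = 4, L = 3,
                       seed = 17)
  expect_identical(r, r2)
})

test_that("reducers are fitted on the training split only (leakage guard)", {
  set.seed(19)
  lf <- toy_features(25, 12, delta = 2, seed = 19)
  Xtr <- lf$matrix[1:30, ]; ytr <- as.character(lf$labels[1:30])
  Xte <- lf$matrix[31:50, ]
  for (arm in c("PCA", "DA")) {
    a <- fsdacam:::reduce_arm(arm, Xtr, ytr, Xte, L = 4,
                              within_mode = "as_printed", ridge = NULL,
                              pca_scale = FALSE)
    b <- fsdacam:::reduce_arm(arm, Xtr, ytr, Xte * 100, L = 4,
                              within_mode = "as_printed", ridge = NULL,
                              pca_scale = FALSE)
    # mutating test-fold features never changes the fitted representation
    expect_identical(a$train, b$train)
    if (arm == "DA") expect_identical(a$basis$projection, b$basis$projection)
  }
  # DA projection is linear with no centering: test block scales exactly
  a <- fsdacam:::reduce_arm("DA", Xtr, ytr, Xte, L = 4,
                            within_mode = "as_printed", ridge = NULL,
                            pca_scale = FALSE)
  b <- fsdacam:::reduce_arm("DA", Xtr, ytr, Xte * 100, L = 4,
                            within_mode = "as_printed", ridge = NULL,
                            pca_scale = FALSE)
  expect_equal(b$test, a$test * 100, tolerance = 1e-8)
})

test_that("orthonormal full-rank reduction leaves the RBF margin arm unchanged", {
  # with L = M the discriminant projection is an orthogonal matrix; the RBF
  # kernel depends only on pairwise distances, so DA and original arms are
  # information-equivalent and the margin classifier yields identical folds
  lf <- toy_features(20, 4, delta = 2, seed = 23)
  r <- cross_validate(lf, arms = c("original", "DA"), folds = 4, L = 4,
                      seed = 23)
  o <- r$folds[r$folds$arm == "original", c("acc", "auc")]
  d <- r$folds[r$folds$arm == "DA", c("acc", "auc")]
  expect_equal(unname(as.matrix(o)), unname(as.matrix(d)), tolerance = 1e-10)
})

test_that("invalid protocol requests raise typed errors", {
  lf <- toy_features(10, 5, delta = 1, seed = 29)
  expect_error(cross_validate(lf, arms = "DA+CV"),
               class = "fsdacam_validation_error")
  expect_error(cross_validate(lf, arms = "bogus"),
               class = "fsdacam_validation_error")
  expect_error(make_stratified_folds(rep(1:2, 5), k = 1),
               class = "fsdacam_validation_error")
})
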