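# Synthetic-data generator.

test_that("feature generation is seeded, reproducible and validated", {
  cfg <- synth_config(n_per_class = 15, M = 20, delta = 2, seed = 301)
  a <- gen_features(cfg)
  b <- gen_features(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_equal(a$class_counts, c(N1 = 15L, N2 = 15L))
  expect_error(synth_config(delta = -1), class = "fsdacam_validation_error")
  expect_error(synth_config(informative_dims = 99, M = 10),
               class = "fsdacam_validation_error")
  expect_error(synth_config(clinical_effect = 2),
               class = "fsdacam_validation_error")
})

test_that("informative dimensions carry the configured separation", {
  cfg <- synth_config(n_per_class = 100, M = 16, informative_dims = 3,
                      delta = 1.5, seed = 303)
  lf <- gen_features(cfg)
  d <- colMeans(lf$matrix[lf$labels == 1, ]) -
       colMeans(lf$matrix[lf$labels == 2, ])
  # empirical mean gap within 3*sigma/sqrt(n) of delta on the informative
  # dimension, near zero elsewhere
  se <- sqrt(2 / 100)
  expect_lt(abs(d[3] - 1.5), 3 * se)
  expect_lt(max(abs(d[-3])), 4 * se)
})

test_that("null separation stays null; strong separation aligns d1", {
  # delta = 0: class-mean difference is noise-level in >= 90% of runs
  hits <- 0L
  for (s in 1:20) {
    cfg <- synth_config(n_per_class = 100, M = 4, delta = 0, seed = 400 + s)
    lf <- gen_features(cfg)
    d <- colMeans(lf$matrix[lf$labels == 1, ]) -
         colMeans(lf$matrix[lf$labels == 2, ])
    t <- max(abs(d)) / sqrt(2 / 100)
    if (t < qnorm(1 - 0.05 / 2 / 4)) hits <- hits + 1L  # Bonferroni over dims
  }
  expect_gte(hits, 18L)

  cfg <- synth_config(n_per_class = 100, M = 8, informative_dims = 2,
                      delta = 10, seed = 421)
  b <- fit_basis(gen_features(cfg), L = 1)
  expect_gte(abs(b$projection[1, 2]), 0.95)
})

test_that("random SPD covariance hits the requested condition number", {
  cfg <- synth_config(n_per_class = 10, M = 12, covariance = "random_spd",
                      condition_number = 50, seed = 307)
  Sigma <- fsdacam:::synth_covariance(cfg)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev) / min(ev), 50, tolerance = 1e-6)
  expect_true(all(ev > 0))
})

test_that("clinical association scales with effect and is monotone", {
  base <- function(e, s) synth_config(n_per_class = 100, M = 4,
                                      clinical_effect = e, seed = s)
  # effect 0: independent (|r| < 0.2 in 95% of seeds)
  ok <- 0L
  for (s in 1:20) {
    cfg <- base(0, 500 + s)
    cl <- gen_clinical(cfg)
    r <- abs(cor(cl$table$score, as.numeric(synth_labels_of(cfg))))
    if (r < 0.2) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
  # effect 1: perfectly separable numeric variable
  cfg1 <- base(1, 521)
  cl1 <- gen_clinical(cfg1)
  y <- synth_labels_of(cfg1)
  expect_gt(min(cl1$table$score[y == 1]), max(cl1$table$score[y == 2]))
  expect_identical(cl1$table$group, ifelse(y == 1, "g1", "g2"))
  # monotone over {0, 0.5, 1}
  rs <- sapply(c(0, 0.5, 1), function(e) {
    cfg <- base(e, 523)
    abs(cor(gen_clinical(cfg)$table$score, as.numeric(synth_labels_of(cfg))))
  })
  expect_true(all(diff(rs) > 0))
  # schema typing is emitted alongside the table
  expect_equal(gen_clinical(base(0.5, 525))$schema,
               list(score = "numeric", group = "categorical"))
})

test_that("feature maps plant class-dependent blobs with exact GAP features", {
  cfg <- synth_config(n_per_class = 5, n_channels = 8, n_hot_channels = 2,
                      blob_size = 2, map_size = c(6, 6), snr = 100,
                      seed = 311)
  fm <- gen_feature_maps(cfg)
  expect_length(fm$maps, 10)
  # masks sit at opposite corners per class
  expect_true(fm$masks[[1]][1, 1]); expect_false(fm$masks[[1]][6, 6])
  expect_true(fm$masks[[10]][6, 6]); expect_false(fm$masks[[10]][1, 1])
  # GAP of the tensors is the emitted feature matrix, exactly
  for (i in c(1, 10))
    expect_equal(fm$features$matrix[i, ],
                 rowMeans(matrix(fm$maps[[i]]$tensor, nrow = 8)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  # at huge SNR the hot channels dominate their blob region
  t1 <- fm$maps[[1]]$tensor
  expect_gt(min(t1[1:2, 1:2, 1:2]), max(abs(t1[3:8, , ])))
  expect_error(synth_config(blob_size = 9, map_size = c(7, 7)),
               class = "fsdacam_validation_error")
})

test_that("full pipeline direction checks: image vs clinical information", {
  # delta large, effect 0: clinical adds nothing to a near-perfect image arm
  cfg <- synth_config(n_per_class = 30, M = 32, informative_dims = 1:3,
                      delta = 6, clinical_effect = 0, seed = 331)
  lf <- gen_features(cfg)
  cl <- gen_clinical(cfg, lf$labels)
  r <- cross_validate(lf, clinical = cl$table, schema = cl$schema,
                      arms = c("DA", "DA+CV"), folds = 5, L = 4, seed = 331)
  s <- r$summary
  expect_lt(abs(s$acc_mean[s$arm == "DA+CV"] - s$acc_mean[s$arm == "DA"]),
            0.1)
  # delta 0, effect 1: clinical carries everything
  cfg2 <- synth_config(n_per_class = 30, M = 32, delta = 0,
                       clinical_effect = 1, seed = 337)
  lf2 <- gen_features(cfg2)
  cl2 <- gen_clinical(cfg2, lf2$labels)
  r2 <- cross_validate(lf2, clinical = cl2$table, schema = cl2$schema,
                       arms = c("DA", "DA+CV"), folds = 5, L = 4, seed = 337)
  s2 <- r2$summary
  expect_gt(s2$acc_mean[s2$arm == "DA+CV"] - s2$acc_mean[s2$arm == "DA"],
            0.3)
})
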