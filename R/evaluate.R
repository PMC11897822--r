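# Cross-validated comparison protocol.
#
# Six feature arms mirror the comparison design: raw backbone features
# ("original"), PCA-reduced, and Foley-Sammon-reduced ("DA"), each with and
# without concatenated clinical variables ("+CV"). Every reducer and the
# clinical encoder are fitted on the training split of each fold only, so
# no label or test-sample information leaks into the representation.

#' Stratified fold assignment
#'
#' Shuffles each class with the given seed and deals samples round-robin,
#' so fold sizes and class balance are as even as possible and the
#' assignment is a pure function of `(labels, k, seed)`.
#'
#' @param labels class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` integer index vectors (test sets).
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop_validation("folds must be >= 2")
  labels <- as.character(labels)
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      if (length(idx) < k)
        stop_validation(sprintf("class '%s' has fewer samples than folds", cl))
      f <- rep_len(seq_len(k), length(idx))
      for (j in seq_len(k)) folds[[j]] <- c(folds[[j]], idx[f == j])
    }
  })
  lapply(folds, sort)
}

#' The six feature-utilization arms of the comparison protocol
#'
#' Raw backbone features, PCA-reduced and discriminant-reduced features,
#' each with and without concatenated clinical variables.
#' @format character vector of arm names.
#' @export
fsda_arms <- c("original", "original+CV", "PCA", "PCA+CV", "DA", "DA+CV")

# Fit a per-arm reducer on the training rows and return train/test blocks.
reduce_arm <- function(arm, Xtr, ytr, Xte, L, within_mode, ridge, pca_scale) {
  base <- sub("\\+CV$", "", arm)
  if (base == "original") {
    return(list(train = Xtr, test = Xte))
  }
  if (base == "PCA") {
    pr <- stats::prcomp(Xtr, center = TRUE, scale. = pca_scale)
    keep <- seq_len(min(L, ncol(pr$rotation)))
    return(list(train = pr$x[, keep, drop = FALSE],
                test = stats::predict(pr, Xte)[, keep, drop = FALSE]))
  }
  basis <- suppressWarnings(
    fit_basis(labelled_features(Xtr, ytr), L = L,
              within_mode = within_mode, ridge = ridge))
  list(train = project(basis, Xtr), test = project(basis, Xte),
       basis = basis)
}

#' Cross-validated evaluation of the feature-fusion arms
#'
#' Runs stratified k-fold cross-validation for one or more feature arms and
#' reports per-fold and aggregated accuracy (ACC) and area under the ROC
#' curve (AUC). AUC is computed from the continuous scores of the positive
#' class (decision-function values for the margin classifier).
#'
#' @param features a [labelled_features] object.
#' @param clinical optional data.frame of per-sample clinical records
#'   (row i corresponds to sample i); required for any `"+CV"` arm.
#' @param schema named list typing the clinical columns (see
#'   [fit_clinical_encoder()]); required with `clinical`.
#' @param arms character vector drawn from
#'   `c("original", "original+CV", "PCA", "PCA+CV", "DA", "DA+CV")`.
#' @param folds number of folds (default 5).
#' @param L reduced dimension for the PCA and DA arms (default 10).
#' @param seed integer seed controlling fold assignment and classifier
#'   tuning folds.
#' @param classifier `"margin"` or `"linear"` (see [train_classifier()]).
#' @param within_mode,ridge passed to [fit_basis()] for the DA arms.
#' @param pca_scale whether the PCA arms scale features to unit variance on
#'   the training fold (centering is always applied).
#' @param positive label treated as positive for AUC; default is the second
#'   class in label order (by convention the disease/abnormal label).
#' @return an `evaluation_report`: `summary` (arm x metric means and sds),
#'   `folds` (per-fold raw values) and `config` (fingerprint of every
#'   setting, including the seed and positive class).
#' @examples
#' cfg <- synth_config(n_per_class = 20, M = 30, delta = 2, seed = 7)
#' lf <- gen_features(cfg)
#' r <- cross_validate(lf, arms = "DA", folds = 2, L = 3, seed = 7)
#' r$summary
#' @export
cross_validate <- function(features, clinical = NULL, schema = NULL,
                           arms = "DA+CV", folds = 5L, L = 10L, seed = 1L,
                           classifier = c("margin", "linear"),
                           within_mode = c("as_printed", "pooled"),
                           ridge = NULL, pca_scale = FALSE, positive = NULL) {
  stopifnot(inherits(features, "labelled_features"))
  classifier <- match.arg(classifier)
  within_mode <- match.arg(within_mode)
  bad <- setdiff(arms, fsda_arms)
  if (length(bad))
    stop_validation(paste("unknown arms:", paste(bad, collapse = ", ")))
  needs_cv <- any(grepl("\\+CV$", arms))
  if (needs_cv && (is.null(clinical) || is.null(schema)))
    stop_validation("arms with '+CV' require `clinical` and `schema`")
  if (!is.null(clinical) && nrow(clinical) != nrow(features$matrix))
    stop_dimension("clinical table must have one row per sample")
  positive <- positive %||% features$label_order[2]
  if (!positive %in% features$label_order)
    stop_validation("`positive` is not one of the class labels")

  X <- features$matrix
  y <- as.character(features$labels)
  fold_idx <- make_stratified_folds(y, k = folds, seed = seed)

  rows <- list()
  for (f in seq_along(fold_idx)) {
    te <- fold_idx[[f]]
    tr <- setdiff(seq_len(nrow(X)), te)
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop_validation("a fold contains a single class; reduce `folds`")
    enc <- NULL
    if (needs_cv) {
      enc <- fit_clinical_encoder(clinical[tr, , drop = FALSE], schema)
      Vtr <- encode_clinical(enc, clinical[tr, , drop = FALSE])
      Vte <- encode_clinical(enc, clinical[te, , drop = FALSE])
    }
    for (arm in arms) {
      red <- reduce_arm(arm, X[tr, , drop = FALSE], y[tr],
                        X[te, , drop = FALSE], L, within_mode, ridge,
                        pca_scale)
      if (grepl("\\+CV$", arm)) {
        Ztr <- fuse_concat(red$train, Vtr)$vector
        Zte <- fuse_concat(red$test, Vte)$vector
      } else {
        Ztr <- red$train
        Zte <- red$test
      }
      clf <- train_classifier(Ztr, y[tr], kind = classifier,
                              tune_seed = sub_seed(seed, f))
      pred <- predict_scores(clf, Zte)
      acc <- mean(pred$predicted == y[te])
      auc <- auc_from_scores(pred$scores[, positive], y[te] == positive)
      rows[[length(rows) + 1L]] <-
        data.frame(arm = arm, fold = f, acc = acc, auc = auc)
    }
  }
  fold_df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(fold_df, fold_df$arm), function(d) {
    data.frame(arm = d$arm[1],
               acc_mean = mean(d$acc), acc_sd = stats::sd(d$acc),
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc))
  }))
  summ <- summ[match(intersect(arms, summ$arm), summ$arm), , drop = FALSE]
  rownames(summ) <- NULL
  structure(
    list(summary = summ, folds = fold_df,
         config = list(arms = arms, folds = folds, L = L, seed = seed,
                       classifier = classifier, within_mode = within_mode,
                       ridge = ridge, pca_scale = pca_scale,
                       positive = positive,
                       n = nrow(X), M = ncol(X))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d-fold CV, n = %d, M = %d, L = %d, classifier = %s\n",
              x$config$folds, x$config$n, x$config$M, x$config$L,
              x$config$classifier))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s ACC %.3f +/- %.3f   AUC %.3f +/- %.3f\n",
                s$arm[i], s$acc_mean[i], s$acc_sd[i], s$auc_mean[i], s$auc_sd[i]))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (full report) and `report.tsv` (the summary table,
#' rows = arms, columns = metrics) into `dir`.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jp <- file.path(dir, "report.json")
  tp <- file.path(dir, "report.tsv")
  jsonlite::write_json(
    list(summary = report$summary, folds = report$folds,
         config = report$config),
    jp, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  utils::write.table(report$summary, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = jp, tsv = tp))
}
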