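# Synthetic data with controllable statistical structure.
#
# Emulates the regime the method targets — M comparable to or larger than
# N, a few discriminative directions, weakly informative clinical
# variables — plus planted-blob feature maps standing in for annotated
# localization data. All randomness flows from one master seed through
# independent sub-streams, so each generator is reproducible in isolation.

#' Configuration of the synthetic-data generator
#'
#' @param n_per_class samples per class (default 50).
#' @param M feature dimension (default 512, the ResNet18-sized regime).
#' @param informative_dims feature indices whose class means differ
#'   (default `1:5`).
#' @param delta class-mean separation per informative dimension, in units
#'   of the within-class standard deviation of that dimension (default 1).
#' @param covariance `"identity"` or `"random_spd"` within-class
#'   covariance shared by both classes.
#' @param condition_number condition number of the random SPD covariance
#'   (default 10).
#' @param clinical_effect association strength in `[0, 1]` between the
#'   clinical variables and the label: 0 = independent, 1 = fully
#'   determined.
#' @param blob_size side length of the planted hot square (default 3).
#' @param map_size feature-map spatial size `(H, W)` (default 7 x 7).
#' @param image_size nominal image size for CAM resizing (default 28 x 28).
#' @param n_channels number of feature-map channels (default 16).
#' @param n_hot_channels channels carrying each class's blob (default 4).
#' @param snr blob amplitude over noise standard deviation (default 3).
#' @param seed master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 50L, M = 512L,
                         informative_dims = seq_len(min(5, M)), delta = 1,
                         covariance = c("identity", "random_spd"),
                         condition_number = 10,
                         clinical_effect = 0.5,
                         blob_size = 3L, map_size = c(7L, 7L),
                         image_size = c(28L, 28L),
                         n_channels = 16L, n_hot_channels = 4L,
                         snr = 3, seed = 1L) {
  covariance <- match.arg(covariance)
  cfg <- list(n_per_class = as.integer(n_per_class), M = as.integer(M),
              informative_dims = as.integer(informative_dims), delta = delta,
              covariance = covariance, condition_number = condition_number,
              clinical_effect = clinical_effect,
              blob_size = as.integer(blob_size),
              map_size = as.integer(map_size),
              image_size = as.integer(image_size),
              n_channels = as.integer(n_channels),
              n_hot_channels = as.integer(n_hot_channels),
              snr = snr, seed = as.integer(seed))
  if (cfg$n_per_class < 1L) stop_validation("n_per_class must be >= 1")
  if (cfg$delta < 0) stop_validation("delta must be >= 0")
  if (any(cfg$informative_dims < 1L | cfg$informative_dims > cfg$M))
    stop_validation("informative_dims out of range")
  if (cfg$clinical_effect < 0 || cfg$clinical_effect > 1)
    stop_validation("clinical_effect must be in [0, 1]")
  if (any(cfg$blob_size > cfg$map_size))
    stop_validation("blob larger than the feature map")
  if (2L * cfg$n_hot_channels > cfg$n_channels)
    stop_validation("need n_channels >= 2 * n_hot_channels")
  structure(cfg, class = "synth_config")
}

synth_labels <- function(cfg) rep(1:2, each = cfg$n_per_class)

# shared within-class covariance; random SPD draws a random orthogonal
# frame with log-spaced eigenvalues spanning the condition number
synth_covariance <- function(cfg) {
  if (cfg$covariance == "identity") return(NULL)
  with_seed(sub_seed(cfg$seed, 101L), {
    Q <- qr.Q(qr(matrix(stats::rnorm(cfg$M^2), cfg$M)))
    ev <- exp(seq(log(cfg$condition_number), log(1), length.out = cfg$M))
    Q %*% (ev * t(Q))
  })
}

#' Generate class-conditional Gaussian features
#'
#' Both classes share the configured covariance; only `informative_dims`
#' differ in mean, by `delta` within-class standard deviations. Class 1
#' sits at the origin-shifted `+delta/2`, class 2 at `-delta/2`.
#'
#' @param cfg a [synth_config].
#' @return a [labelled_features] with labels `1` and `2`.
#' @export
gen_features <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  Sigma <- synth_covariance(cfg)
  n <- 2L * cfg$n_per_class
  labels <- synth_labels(cfg)
  X <- with_seed(sub_seed(cfg$seed, 1L), {
    Z <- matrix(stats::rnorm(n * cfg$M), n, cfg$M)
    if (!is.null(Sigma)) Z <- Z %*% chol(Sigma)
    Z
  })
  sds <- if (is.null(Sigma)) rep(1, cfg$M) else sqrt(diag(Sigma))
  shift <- numeric(cfg$M)
  shift[cfg$informative_dims] <- cfg$delta / 2 * sds[cfg$informative_dims]
  X[labels == 1L, ] <- sweep(X[labels == 1L, , drop = FALSE], 2L, shift, "+")
  X[labels == 2L, ] <- sweep(X[labels == 2L, , drop = FALSE], 2L, shift, "-")
  labelled_features(X, labels)
}

#' Generate a clinical table correlated with the labels
#'
#' One numeric variable (`score`) and one categorical variable (`group`).
#' The numeric variable is `effect * s + (1 - effect) * noise` with
#' `s = +1/-1` by class, so `effect = 0` is label-independent and
#' `effect = 1` perfectly separable. The categorical variable equals the
#' class name but flips with probability `(1 - effect)/2`.
#'
#' @param cfg a [synth_config].
#' @param labels class labels (default: the configuration's own).
#' @return list with `table` (data.frame `sample_id`, `score`, `group`),
#'   `schema` (named list) and `text` (one sentence per sample for the
#'   embedding fusion strategy).
#' @export
gen_clinical <- function(cfg, labels = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- labels %||% synth_labels(cfg)
  e <- cfg$clinical_effect
  n <- length(labels)
  lev <- sort(unique(as.character(labels)))
  s <- ifelse(as.character(labels) == lev[1], 1, -1)
  with_seed(sub_seed(cfg$seed, 2L), {
    score <- e * s + (1 - e) * stats::rnorm(n)
    flip <- stats::runif(n) < (1 - e) / 2
    grp <- ifelse(xor(s == 1, flip), "g1", "g2")
  })
  table <- data.frame(sample_id = seq_len(n), score = score, group = grp,
                      stringsAsFactors = FALSE)
  schema <- list(score = "numeric", group = "categorical")
  text <- sprintf("patient %d score %.2f group %s", table$sample_id,
                  table$score, table$group)
  list(table = table, schema = schema, text = text)
}

blob_location <- function(cfg, class) {
  b <- cfg$blob_size
  if (class == 1L) list(rows = 1:b, cols = 1:b)
  else list(rows = (cfg$map_size[1] - b + 1):cfg$map_size[1],
            cols = (cfg$map_size[2] - b + 1):cfg$map_size[2])
}

#' Generate planted-blob feature maps
#'
#' Each sample's map is unit-variance Gaussian noise over
#' `n_channels x H x W`; a hot square of amplitude `snr` (times the noise
#' sd) is added at a class-dependent corner in a class-specific subset of
#' channels (channels `1..n_hot` for class 1, the next `n_hot` for class
#' 2). Channel-wise GAP of each map is emitted as the pooled feature
#' vector, so the CAM consistency contract holds by construction. Ground
#' -truth masks are returned for localization scoring at both the map and
#' the image resolution.
#'
#' @param cfg a [synth_config].
#' @param labels class labels (default: the configuration's own).
#' @return list with `maps` (list of [feature_map]), `features`
#'   ([labelled_features] of GAP vectors), `masks` (list of H x W logical
#'   matrices) and `image_masks` (image-sized logical matrices).
#' @export
gen_feature_maps <- function(cfg, labels = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- labels %||% synth_labels(cfg)
  H <- cfg$map_size[1]; W <- cfg$map_size[2]
  nc <- cfg$n_channels
  hot <- list(`1` = seq_len(cfg$n_hot_channels),
              `2` = cfg$n_hot_channels + seq_len(cfg$n_hot_channels))
  maps <- vector("list", length(labels))
  masks <- vector("list", length(labels))
  image_masks <- vector("list", length(labels))
  with_seed(sub_seed(cfg$seed, 3L), {
    for (i in seq_along(labels)) {
      cl <- as.integer(labels[i])
      tensor <- array(stats::rnorm(nc * H * W), dim = c(nc, H, W))
      loc <- blob_location(cfg, cl)
      tensor[hot[[as.character(cl)]], loc$rows, loc$cols] <-
        tensor[hot[[as.character(cl)]], loc$rows, loc$cols] + cfg$snr
      maps[[i]] <- feature_map(tensor, image_size = cfg$image_size)
      mk <- matrix(FALSE, H, W)
      mk[loc$rows, loc$cols] <- TRUE
      masks[[i]] <- mk
      image_masks[[i]] <-
        resize_map(mk * 1, cfg$image_size, method = "nearest") > 0.5
    }
  })
  feats <- t(vapply(maps, function(m) m$pooled, numeric(nc)))
  list(maps = maps, features = labelled_features(feats, labels),
       masks = masks, image_masks = image_masks)
}
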