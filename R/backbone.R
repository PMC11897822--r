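# Pluggable frozen feature-extractor adapters.
#
# Real deep backbones (ResNet18 / VGGNet16 / ViT) are optional extras: the
# named specs record the published resize targets and feature widths, but
# inference needs a deep-learning backend this package does not require.
# The shipped synthetic backbone is a deterministic linear map from image
# blocks to channels, sufficient to exercise the full pipeline (and exact
# about the GAP/pooled-feature consistency the CAM path assumes).

#' Describe a feature-extractor backbone
#'
#' @param name backbone identifier. Known names carry their published
#'   preprocessing metadata: `"resnet18"` (512 x 512 input, M = 512),
#'   `"vgg16"` (224 x 224, M = 4096), `"vit"` (384 x 384, M = 768, no
#'   convolutional feature map), `"synthetic"`.
#' @param input_size `(height, width)` images are resized to.
#' @param feature_dim pooled feature dimension M.
#' @param provides_feature_map whether a last-conv-layer map is available
#'   (required for CAM).
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(name,
                          input_size = NULL, feature_dim = NULL,
                          provides_feature_map = NULL) {
  known <- list(
    resnet18 = list(input_size = c(512L, 512L), feature_dim = 512L,
                    provides_feature_map = TRUE),
    vgg16 = list(input_size = c(224L, 224L), feature_dim = 4096L,
                 provides_feature_map = TRUE),
    vit = list(input_size = c(384L, 384L), feature_dim = 768L,
               provides_feature_map = FALSE))
  k <- known[[name]]
  spec <- list(
    name = name,
    input_size = input_size %||% k$input_size,
    feature_dim = feature_dim %||% k$feature_dim,
    provides_feature_map = provides_feature_map %||% k$provides_feature_map)
  if (is.null(spec$input_size) || is.null(spec$feature_dim))
    stop_validation("input_size and feature_dim are required for unknown backbones")
  structure(spec, class = "backbone_spec")
}

#' Deterministic synthetic backbone
#'
#' A linear, weight-frozen stand-in for a convolutional extractor: the
#' image is average-pooled onto an `map_size` grid and each channel is that
#' grid scaled by a fixed channel weight `1 + cos(2*pi*m/M)/2`. Linear with
#' zero bias, so a blank (all-zero) image maps to an all-zero feature map
#' and pooled vector; identical images always yield identical features.
#'
#' @param feature_dim number of channels M (default 64).
#' @param map_size spatial size `(H, W)` of the feature map (default 7 x 7).
#' @param input_size images are expected at this size (default 28 x 28).
#' @return a `backbone_spec` with the synthetic extractor attached.
#' @export
synthetic_backbone <- function(feature_dim = 64L, map_size = c(7L, 7L),
                               input_size = c(28L, 28L)) {
  spec <- backbone_spec("synthetic", input_size = as.integer(input_size),
                        feature_dim = as.integer(feature_dim),
                        provides_feature_map = TRUE)
  spec$map_size <- as.integer(map_size)
  spec$channel_weights <-
    1 + cos(2 * pi * seq_len(feature_dim) / feature_dim) / 2
  spec
}

block_pool <- function(img, grid) {
  H <- nrow(img); W <- ncol(img)
  ri <- ceiling(seq_len(H) * grid[1] / H)
  ci <- ceiling(seq_len(W) * grid[2] / W)
  out <- matrix(0, grid[1], grid[2])
  cnt <- matrix(0, grid[1], grid[2])
  for (i in seq_len(H)) for (j in seq_len(W)) {
    out[ri[i], ci[j]] <- out[ri[i], ci[j]] + img[i, j]
    cnt[ri[i], ci[j]] <- cnt[ri[i], ci[j]] + 1
  }
  out / pmax(cnt, 1)
}

read_image_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    fsda_stop("reading PNG images needs the 'png' package; install it or pass image matrices directly",
              "fsdacam_missing_dependency_error")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  a
}

#' Extract pooled features (and feature maps) from images
#'
#' @param spec a `backbone_spec`. Only the synthetic backbone can run
#'   in-process; named deep backbones raise an actionable error pointing at
#'   the required optional backend.
#' @param images list of grayscale matrices (values in `[0, 1]`) or a
#'   character vector of PNG paths.
#' @param continue_on_error if `TRUE`, unreadable images are skipped with a
#'   warning instead of aborting the batch.
#' @return list with `features` (N x M matrix of pooled vectors) and
#'   `maps` (list of [feature_map] objects).
#' @export
extract_features <- function(spec, images, continue_on_error = FALSE) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$name != "synthetic")
    fsda_stop(sprintf(
      "backbone '%s' needs a deep-learning backend; install the optional torch-based extras or use synthetic_backbone()",
      spec$name), "fsdacam_missing_dependency_error")
  if (is.character(images)) images <- as.list(images)
  maps <- vector("list", length(images))
  keep <- logical(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    ok <- tryCatch({
      if (is.character(img)) img <- read_image_gray(img)
      img <- as.matrix(img)
      assert_finite(img, sprintf("image %d", i))
      pooled_grid <- block_pool(img, spec$map_size)
      tensor <- array(0, dim = c(spec$feature_dim, spec$map_size))
      for (m in seq_len(spec$feature_dim))
        tensor[m, , ] <- pooled_grid * spec$channel_weights[m]
      maps[[i]] <- feature_map(tensor, image_size = dim(img))
      TRUE
    }, error = function(e) {
      if (!continue_on_error) stop(e)
      warning(sprintf("image %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
    keep[i] <- isTRUE(ok)
  }
  maps <- maps[keep]
  feats <- if (length(maps))
    t(vapply(maps, function(m) m$pooled, numeric(spec$feature_dim)))
  else matrix(0, 0, spec$feature_dim)
  list(features = feats, maps = maps)
}
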