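# Class activation maps through the dimension-reduced feature space.
#
# Standard CAM weights the channels of the last convolutional feature map
# with the classifier weights attached to the pooled features. After
# discriminant reduction the classifier acts on P y, not y, so its image
# -block weights w_hat_i live in the L-dimensional subspace; they are
# back-projected to channel space with w' = P' w_hat_i and the relevance
# map is R' = reshape(F_hat' w', H x W), then interpolated to image size.

#' Last-convolutional-layer feature map container
#'
#' Holds the M x H x W tensor `F`, its M x (H*W) flattening `F_hat`, and
#' the channel-wise spatial mean (global average pooling, GAP) which must
#' reproduce the backbone feature vector the projection was fitted on —
#' the consistency the CAM derivation assumes. If `pooled` is supplied and
#' disagrees with GAP(F) beyond 1e-5 a backbone-adapter-mismatch warning is
#' raised.
#'
#' @param tensor numeric array with dim `c(M, H, W)`.
#' @param image_size optional `(height, width)` of the source image.
#' @param pooled optional externally supplied pooled feature vector.
#' @return object of class `feature_map` with elements `tensor`,
#'   `flattened`, `pooled`, `shape` and `image_size`.
#' @export
feature_map <- function(tensor, image_size = NULL, pooled = NULL) {
  if (length(dim(tensor)) != 3L)
    stop_dimension("tensor must be a 3-d array (channels, height, width)")
  assert_finite(tensor, "feature map")
  d <- dim(tensor)
  flat <- matrix(tensor, nrow = d[1])      # columns: spatial sites (h fastest)
  gap <- rowMeans(flat)
  if (!is.null(pooled)) {
    if (length(pooled) != d[1])
      stop_dimension("pooled vector length must equal channel count")
    if (max(abs(pooled - gap)) > 1e-5)
      warning("pooled features disagree with GAP of the feature map beyond 1e-5 (backbone adapter mismatch)",
              call. = FALSE)
  } else {
    pooled <- gap
  }
  structure(list(tensor = tensor, flattened = flat, pooled = pooled,
                 shape = c(M = d[1], H = d[2], W = d[3]),
                 image_size = image_size),
            class = "feature_map")
}

#' Class activation map for a dimension-reduced linear classifier
#'
#' Implements the projection-aware CAM: (1) pool the feature map to `y`;
#' (2) reduce, `ybar = P y`; (3) fuse with the clinical block,
#' `z = (ybar', v')'`; (4) score, `u = W'z + bias`, and take the predicted
#' class `i` (or `class` if given); (5) take the first `L` components
#' `w_hat_i` of `w_i`; (6) back-project, `w' = P' w_hat_i`; (7) form
#' `R' = reshape(F_hat' w', H x W)`; (8) interpolate `R'` to the image
#' size. The classifier bias and the clinical-block weights never enter
#' the map; the clinical contribution to the class score is reported as a
#' scalar side channel so the user can see how much evidence the map
#' cannot show.
#'
#' @param fmap a [feature_map].
#' @param basis a [discriminant_basis] whose `M` equals the channel count.
#' @param classifier an `fsda_classifier` of kind `"linear"`.
#' @param clinical encoded clinical vector for this sample (may be empty).
#' @param class optional class index (1 or 2) overriding the predicted one.
#' @param target_size `(height, width)` of the output map; defaults to the
#'   feature map's `image_size`, falling back to `(H, W)`.
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @return object of class `cam_result`: `weight_back` (`w'`), `raw_map`
#'   (`R'`), `resized_map` (`R`), `predicted_class`, `predicted_label`,
#'   `scores`, `clinical_contribution` and `normalization` (min/max of the
#'   raw map, recorded for display).
#' @export
compute_cam <- function(fmap, basis, classifier, clinical = numeric(0),
                        class = NULL, target_size = NULL,
                        interp = c("bilinear", "nearest")) {
  stopifnot(inherits(fmap, "feature_map"),
            inherits(basis, "discriminant_basis"),
            inherits(classifier, "fsda_classifier"))
  interp <- match.arg(interp)
  if (classifier$kind != "linear")
    fsda_stop("CAM requires the linear (fully connected) classifier kind",
              "fsdacam_unsupported_classifier_error")
  if (basis$M != fmap$shape[["M"]])
    stop_dimension("basis feature dimension must equal the channel count")
  L <- basis$L
  if (L > nrow(classifier$weights))
    stop_dimension("classifier input is narrower than the image block L")

  y <- fmap$pooled
  ybar <- project(basis, y)
  z <- c(ybar, as.numeric(clinical))
  if (length(z) != nrow(classifier$weights))
    stop_dimension("fused vector width does not match classifier weights")
  u <- as.numeric(crossprod(classifier$weights, z)) + classifier$bias
  i <- class %||% which.max(u)
  if (!i %in% seq_along(classifier$classes))
    stop_validation("`class` must index one of the classifier's classes")
  w_i <- classifier$weights[, i]
  w_hat <- w_i[seq_len(L)]
  clin_contrib <- if (length(z) > L) sum(w_i[-seq_len(L)] * z[-seq_len(L)]) else 0
  w_back <- as.numeric(crossprod(basis$projection, w_hat))
  # channel-wise accumulation (not BLAS) so the weighted sum has a fixed
  # IEEE evaluation order: reruns and reference implementations agree bitwise
  raw <- matrix(0, fmap$shape[["H"]], fmap$shape[["W"]])
  for (m in seq_len(fmap$shape[["M"]]))
    raw <- raw + w_back[m] * fmap$tensor[m, , ]
  target <- target_size %||% fmap$image_size %||% dim(raw)
  resized <- resize_map(raw, target, method = interp)
  structure(
    list(weight_back = w_back, raw_map = raw, resized_map = resized,
         predicted_class = i, predicted_label = classifier$classes[i],
         scores = u, clinical_contribution = clin_contrib,
         normalization = c(min = min(raw), max = max(raw))),
    class = "cam_result")
}

#' Resize a relevance map by interpolation
#'
#' Bilinear interpolation uses corner-aligned sampling, so constant maps
#' are preserved exactly and values never leave the input range; nearest
#' -neighbour upscaling by an integer factor k replicates each cell k x k.
#'
#' @param raw H x W numeric matrix.
#' @param target `(height, width)`, both >= 1.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return numeric matrix of dimension `target`.
#' @export
resize_map <- function(raw, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L) || anyNA(target))
    stop_validation("target must be two integers >= 1")
  H <- nrow(raw); W <- ncol(raw)
  th <- target[1]; tw <- target[2]
  if (method == "nearest") {
    ri <- ceiling(seq_len(th) * H / th)
    ci <- ceiling(seq_len(tw) * W / tw)
    return(raw[ri, ci, drop = FALSE])
  }
  src <- function(t, Tn, S) {
    if (Tn == 1L) (S + 1) / 2 else 1 + (t - 1) * (S - 1) / (Tn - 1)
  }
  rs <- src(seq_len(th), th, H)
  cs <- src(seq_len(tw), tw, W)
  r0 <- pmin(pmax(floor(rs), 1L), H); r1 <- pmin(r0 + 1L, H)
  c0 <- pmin(pmax(floor(cs), 1L), W); c1 <- pmin(c0 + 1L, W)
  fr <- rs - r0; fc <- cs - c0
  out <- matrix(0, th, tw)
  for (j in seq_len(tw)) {
    a <- raw[r0, c0[j]] * (1 - fr) + raw[r1, c0[j]] * fr
    b <- raw[r0, c1[j]] * (1 - fr) + raw[r1, c1[j]] * fr
    out[, j] <- a * (1 - fc[j]) + b * fc[j]
  }
  out
}

# blue -> cyan -> yellow -> red ramp on [0, 1], vectorized
heat_colormap <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(3 * v - 1.5, 0), 1)
  g <- pmin(pmax(1.5 - abs(3 * v - 1.5), 0), 1)
  b <- pmin(pmax(1.5 - 3 * v, 0), 1)
  cbind(r, g, b)
}

#' Overlay a relevance map onto an image
#'
#' Min-max normalizes the map to `[0, 1]` (a constant map normalizes to
#' all-zeros with a warning), colors it with a blue-to-red ramp, and
#' alpha-blends it onto the image. `alpha = 0` returns the image pixels
#' unchanged; `alpha = 1` returns the pure heat layer. Deterministic for
#' fixed inputs.
#'
#' @param map image-sized numeric matrix.
#' @param image grayscale H x W matrix or H x W x 3 array, values in
#'   `[0, 1]`.
#' @param alpha blend weight of the heat layer in `[0, 1]`.
#' @return H x W x 3 numeric array (RGB in `[0, 1]`).
#' @seealso [write_ppm()] to persist the rendering as plain text.
#' @export
overlay <- function(map, image, alpha = 0.5) {
  map <- as.matrix(map)
  if (alpha < 0 || alpha > 1) stop_validation("alpha must be in [0, 1]")
  if (length(dim(image)) == 2L) {
    img <- array(rep(as.matrix(image), 3L), dim = c(dim(image), 3L))
  } else if (length(dim(image)) == 3L && dim(image)[3] == 3L) {
    img <- image
  } else stop_validation("image must be H x W or H x W x 3")
  if (!all(dim(map) == dim(img)[1:2]))
    stop_dimension("map and image spatial sizes differ")
  rng <- range(map)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant relevance map; normalized to all-zeros", call. = FALSE)
    norm <- matrix(0, nrow(map), ncol(map))
  } else {
    norm <- (map - rng[1]) / diff(rng)
  }
  heat <- array(heat_colormap(as.numeric(norm)), dim = c(dim(map), 3L))
  out <- (1 - alpha) * img + alpha * heat
  pmin(pmax(out, 0), 1)
}

#' Write an RGB array as a plain-text PPM (P3) image
#'
#' @param img H x W x 3 numeric array with values in `[0, 1]`.
#' @param path output path.
#' @param maxval maximum sample value (default 255).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path, maxval = 255L) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_validation("img must be H x W x 3")
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), as.character(maxval)), con)
  # one image row per line, pixels left-to-right as "r g b" triples
  for (i in seq_len(h)) {
    row <- as.vector(rbind(px[i, , 1], px[i, , 2], px[i, , 3]))
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(path)
}
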