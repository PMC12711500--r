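# Grad-CAM at the SPPF (or CSP) output: channel weights are the spatial
# means of the target-class logit's gradient w.r.t. the feature map; the
# class-activation map is the ReLU of the weighted channel sum.

# alpha_k = mean_{h,w} dA[h,w,k]; raw = ReLU(sum_k alpha_k A[,,k])
cam_from_activations <- function(a, da) {
  hw <- dim(a)[1] * dim(a)[2]
  alpha <- colMeans(matrix(da, hw, dim(a)[3]))
  raw <- matrix(matrix(a, hw, dim(a)[3]) %*% alpha, dim(a)[1], dim(a)[2])
  list(alpha = alpha, raw = pmax(raw, 0))
}

# min-max to [0, 1]; all-zero maps stay zero, constant non-zero maps
# saturate to one
normalize_cam <- function(raw) {
  mx <- max(raw)
  mn <- min(raw)
  if (mx == mn) {
    if (mx == 0) raw else raw / mx
  } else {
    (raw - mn) / (mx - mn)
  }
}

#' Grad-CAM heatmap
#'
#' Computes the gradient of the target class's logit with respect to the
#' SPPF block's output feature map (the model's final convolutional stage),
#' spatially averages it into per-channel weights, and forms the ReLU of the
#' weighted channel sum. The map is min-max normalized per image to `[0, 1]`
#' and bilinearly upsampled to the input resolution. Model parameters are
#' never modified. Deterministic (evaluation mode).
#'
#' @param model A `caspnet` model with a convolutional stage (every variant
#'   except `vit_only`).
#' @param image A single image: `(H, W, 3)` in `[0, 1]`, or preprocessed
#'   when `preprocess = FALSE`.
#' @param target_class Integer class index in `1..num_classes`.
#' @param layer `"sppf"` (default; the final conv stage) or `"csp"`.
#' @param preprocess Apply [eval_transform()] first.
#' @return An object of class `caspnet_heatmap`: `values` (normalized grid,
#'   e.g. 14 x 14), `raw` (pre-normalization, non-negative), `upsampled`
#'   (input resolution), `alpha`, `target_class`, `layer`, `probs`.
#' @export
grad_cam <- function(model, image, target_class,
                     layer = c("sppf", "csp"), preprocess = TRUE) {
  layer <- match.arg(layer)
  k <- model$cfg$num_classes
  if (target_class < 1 || target_class > k) {
    stop_caspnet(sprintf("target_class must lie in [1, %d]", k))
  }
  if (is.null(model$params[[layer]])) {
    stop_caspnet(sprintf("variant '%s' has no %s stage",
                         model$cfg$variant, layer))
  }
  if (length(dim(image)) == 4L) {
    if (dim(image)[4] != 1L) stop_caspnet("grad_cam() takes a single image")
    image <- array(image, dim(image)[1:3])
  }
  side <- model$cfg$image_size
  x <- if (preprocess) eval_transform(image, size = side) else image
  fw <- caspnet_forward(model, x, training = FALSE, keep_cache = TRUE,
                        collect = TRUE)
  dlogits <- matrix(0, 1, k)
  dlogits[1, target_class] <- 1
  bw <- caspnet_backward(model, fw, dlogits, stop_after = layer)
  a <- array(fw$outputs[[layer]], dim(fw$outputs[[layer]])[1:3])
  da <- array(bw$dstage, dim(bw$dstage)[1:3])
  cam <- cam_from_activations(a, da)
  if (all(cam$raw == 0)) {
    message("grad_cam: gradient is zero everywhere; heatmap is all-zero")
  }
  values <- normalize_cam(cam$raw)
  up <- bilinear_resize(array(values, c(dim(values), 1L)),
                        dim(x)[1], dim(x)[2])[, , 1]
  structure(list(values = values, raw = cam$raw, upsampled = up,
                 alpha = cam$alpha, target_class = target_class,
                 layer = layer,
                 probs = drop(softmax_rows(fw$logits))),
            class = "caspnet_heatmap")
}

#' @export
print.caspnet_heatmap <- function(x, ...) {
  cat(sprintf(
    "Grad-CAM heatmap (%dx%d grid at the %s output, class %d, p = %.3f)\n",
    nrow(x$values), ncol(x$values), x$layer, x$target_class,
    x$probs[x$target_class]))
  invisible(x)
}

#' @export
plot.caspnet_heatmap <- function(x, ...) {
  image(t(x$upsampled[nrow(x$upsampled):1, , drop = FALSE]),
        col = heat.colors(64, rev = TRUE), axes = FALSE,
        main = sprintf("Grad-CAM (class %d, %s)", x$target_class, x$layer))
  invisible(x)
}

#' Save a heatmap (and optional overlay) as PNG
#'
#' @param heatmap A `caspnet_heatmap`.
#' @param path Output path for the grayscale heatmap PNG.
#' @param image Optional `(H, W, 3)` image (input resolution) to alpha-blend
#'   under a red-blue rendering, written to `overlay_path`.
#' @param overlay_path Output path for the overlay (default: `path` with an
#'   `_overlay` suffix).
#' @param alpha Blend weight of the heatmap in the overlay.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path, image = NULL,
                              overlay_path = NULL, alpha = 0.45) {
  stopifnot(inherits(heatmap, "caspnet_heatmap"))
  png::writePNG(heatmap$upsampled, path)
  if (!is.null(image)) {
    overlay_path <- overlay_path %||% sub("(\\.png)?$", "_overlay.png",
                                          path, ignore.case = TRUE)
    h <- heatmap$upsampled
    if (!all(dim(h) == dim(image)[1:2])) {
      image <- bilinear_resize(image, dim(h)[1], dim(h)[2])
    }
    col <- array(0, dim(image))
    col[, , 1] <- h                       # red = high activation
    col[, , 3] <- 1 - h                   # blue = low
    out <- (1 - alpha) * image + alpha * col
    png::writePNG(pmin(pmax(out, 0), 1), overlay_path)
  }
  invisible(path)
}

#' Localization score of a heatmap against a ground-truth mask
#'
#' Reports the fraction of total heatmap mass falling inside the mask and
#' inside the mask dilated by a disc of radius `margin` pixels, along with
#' the corresponding area fractions (the scores a uniform heatmap would
#' attain).
#'
#' @param heatmap A `caspnet_heatmap` or a non-negative matrix at input
#'   resolution.
#' @param mask Binary matrix (same size as the upsampled heatmap).
#' @param margin Dilation radius in pixels; defaults to 10% of the shorter
#'   mask edge.
#' @return List with `in_mask`, `in_dilated`, `mask_fraction`,
#'   `dilated_fraction`.
#' @export
localization_check <- function(heatmap, mask, margin = NULL) {
  h <- if (inherits(heatmap, "caspnet_heatmap")) heatmap$upsampled else
    heatmap
  mask <- (as.matrix(mask) > 0) * 1
  if (!all(dim(h) == dim(mask))) {
    stop_caspnet(sprintf(
      "heatmap (%dx%d) and mask (%dx%d) sizes differ",
      nrow(h), ncol(h), nrow(mask), ncol(mask)))
  }
  margin <- margin %||% max(1L, round(0.1 * min(dim(mask))))
  brush <- EBImage::makeBrush(2L * as.integer(margin) + 1L, "disc")
  dil <- EBImage::dilate(mask, brush)
  total <- sum(h)
  if (total == 0) {
    message("localization_check: heatmap has zero mass")
    return(list(in_mask = NA_real_, in_dilated = NA_real_,
                mask_fraction = mean(mask), dilated_fraction = mean(dil)))
  }
  list(in_mask = sum(h * mask) / total,
       in_dilated = sum(h * dil) / total,
       mask_fraction = mean(mask),
       dilated_fraction = mean(dil))
}
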