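# Geometric warps share one bilinear sampler so augmentation, evaluation
# resizing and heatmap upsampling stay mutually consistent.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

# Bilinear resample of (H, W, C) to (out_h, out_w); half-pixel-centred
# source coordinates, edge clamped.
bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  sy <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  sx <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  y0 <- pmin(pmax(floor(sy), 1), d[1])
  x0 <- pmin(pmax(floor(sx), 1), d[2])
  y1 <- pmin(y0 + 1, d[1])
  x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(sy - y0, 0), 1)
  wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    v <- img[, , ch]
    out[, , ch] <-
      outer(1 - wy, 1 - wx) * v[y0, x0] + outer(1 - wy, wx) * v[y0, x1] +
      outer(wy, 1 - wx) * v[y1, x0] + outer(wy, wx) * v[y1, x1]
  }
  out
}

# Rotate about the image centre by `deg` (counter-clockwise), bilinear
# sampling, out-of-bounds pixels set to `fill` (one value per channel).
rotate_image <- function(img, deg, fill) {
  d <- dim(img)
  th <- deg * pi / 180
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  gy <- matrix(seq_len(d[1]) - cy, d[1], d[2])
  gx <- matrix(rep(seq_len(d[2]) - cx, each = d[1]), d[1], d[2])
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  y0 <- floor(sy)
  x0 <- floor(sx)
  wy <- sy - y0
  wx <- sx - x0
  valid <- sy >= 1 & sy <= d[1] & sx >= 1 & sx <= d[2]
  cl <- function(v, lim) pmin(pmax(v, 1), lim)
  i00 <- cbind(as.vector(cl(y0, d[1])), as.vector(cl(x0, d[2])))
  i01 <- cbind(as.vector(cl(y0, d[1])), as.vector(cl(x0 + 1, d[2])))
  i10 <- cbind(as.vector(cl(y0 + 1, d[1])), as.vector(cl(x0, d[2])))
  i11 <- cbind(as.vector(cl(y0 + 1, d[1])), as.vector(cl(x0 + 1, d[2])))
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    v <- img[, , ch]
    res <- (1 - wy) * (1 - wx) * v[i00] + (1 - wy) * wx * v[i01] +
      wy * (1 - wx) * v[i10] + wy * wx * v[i11]
    res[!valid] <- fill[ch]
    out[, , ch] <- matrix(res, d[1], d[2])
  }
  out
}

#' Training-time augmentation configuration
#'
#' The published recipe: random-resized crop to 224, horizontal and vertical
#' flips at p = 0.5, rotation uniform in +/-20 degrees, and colour jitter
#' with brightness/contrast/saturation/hue factors of 0.1 each. The crop
#' scale range (area fraction of the source image) defaults to (0.6, 1.0)
#' so the cell stays mostly in frame; rotation fill defaults to the image's
#' median border colour.
#'
#' @param crop_size Output edge in pixels.
#' @param hflip_p,vflip_p Flip probabilities.
#' @param rotation_deg Maximum absolute rotation in degrees.
#' @param jitter Named numeric vector `brightness`, `contrast`,
#'   `saturation`, `hue` (factors, all >= 0).
#' @param crop_scale Area-fraction range of the random crop.
#' @param crop_aspect Aspect-ratio range of the random crop.
#' @param rotation_fill `"median"` (median border colour) or a length-3
#'   numeric colour.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_size = 224L,
                                hflip_p = 0.5, vflip_p = 0.5,
                                rotation_deg = 20,
                                jitter = c(brightness = 0.1, contrast = 0.1,
                                           saturation = 0.1, hue = 0.1),
                                crop_scale = c(0.6, 1.0),
                                crop_aspect = c(3 / 4, 4 / 3),
                                rotation_fill = "median") {
  check_prob(hflip_p, "hflip_p")
  check_prob(vflip_p, "vflip_p")
  if (rotation_deg < 0) stop_caspnet("'rotation_deg' must be >= 0")
  if (any(jitter < 0)) stop_caspnet("jitter factors must be >= 0")
  structure(list(crop_size = check_count(crop_size, "crop_size"),
                 hflip_p = hflip_p, vflip_p = vflip_p,
                 rotation_deg = rotation_deg, jitter = jitter,
                 crop_scale = crop_scale, crop_aspect = crop_aspect,
                 rotation_fill = rotation_fill),
            class = "augmentation_config")
}

median_border <- function(img) {
  d <- dim(img)
  vapply(seq_len(d[3]), function(ch) {
    v <- img[, , ch]
    median(c(v[1, ], v[d[1], ], v[, 1], v[, d[2]]))
  }, numeric(1))
}

#' Randomly augment a training image
#'
#' Applies, in order: random-resized crop to `crop_size`, horizontal flip,
#' vertical flip, rotation, colour jitter. Uses the session RNG; seed via
#' `set.seed()` (the training loop seeds per epoch). Degenerate crop draws
#' fall back to a centre crop.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param cfg An [augmentation_config()].
#' @return A `(crop_size, crop_size, 3)` array in `[0, 1]`.
#' @export
augment <- function(image, cfg = augmentation_config()) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop_caspnet("augment() expects an (H, W, 3) image")
  }
  area <- d[1] * d[2]
  crop <- NULL
  for (i in 1:10) {
    sc <- runif(1, cfg$crop_scale[1], cfg$crop_scale[2])
    ar <- exp(runif(1, log(cfg$crop_aspect[1]), log(cfg$crop_aspect[2])))
    ch_ <- round(sqrt(area * sc / ar))
    cw <- round(sqrt(area * sc * ar))
    if (ch_ >= 1 && cw >= 1 && ch_ <= d[1] && cw <= d[2]) {
      y <- sample.int(d[1] - ch_ + 1L, 1L)
      x <- sample.int(d[2] - cw + 1L, 1L)
      crop <- image[y:(y + ch_ - 1L), x:(x + cw - 1L), , drop = FALSE]
      break
    }
  }
  if (is.null(crop)) {    # fallback: central square crop
    side <- min(d[1], d[2])
    y <- (d[1] - side) %/% 2L + 1L
    x <- (d[2] - side) %/% 2L + 1L
    crop <- image[y:(y + side - 1L), x:(x + side - 1L), , drop = FALSE]
  }
  out <- bilinear_resize(crop, cfg$crop_size, cfg$crop_size)
  if (runif(1) < cfg$hflip_p) out <- out[, dim(out)[2]:1, , drop = FALSE]
  if (runif(1) < cfg$vflip_p) out <- out[dim(out)[1]:1, , , drop = FALSE]
  if (cfg$rotation_deg > 0) {
    ang <- runif(1, -cfg$rotation_deg, cfg$rotation_deg)
    fill <- if (identical(cfg$rotation_fill, "median")) {
      median_border(out)
    } else {
      cfg$rotation_fill
    }
    out <- rotate_image(out, ang, fill)
  }
  out <- color_jitter(out, cfg$jitter)
  pmin(pmax(out, 0), 1)
}

color_jitter <- function(img, jitter) {
  if (jitter["brightness"] > 0) {
    img <- img * runif(1, 1 - jitter["brightness"], 1 + jitter["brightness"])
  }
  if (jitter["contrast"] > 0) {
    g <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    img <- (img - g) * runif(1, 1 - jitter["contrast"],
                             1 + jitter["contrast"]) + g
  }
  if (jitter["saturation"] > 0) {
    gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    f <- runif(1, 1 - jitter["saturation"], 1 + jitter["saturation"])
    for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * f
  }
  if (jitter["hue"] > 0) {
    shift <- runif(1, -jitter["hue"], jitter["hue"])
    img <- shift_hue(pmin(pmax(img, 0), 1), shift)
  }
  img
}

shift_hue <- function(img, shift) {
  d <- dim(img)
  rgbm <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + shift) %% 1
  cols <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  out <- grDevices::col2rgb(cols) / 255
  array(c(out[1, ], out[2, ], out[3, ]), d)
}

#' Deterministic evaluation transform
#'
#' Bilinear resize to `size` x `size`, then per-channel standardization:
#' `(x - mean) / std`. Defaults are the widely used natural-image statistics;
#' override with dataset-computed values if preferred.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param size Output edge in pixels.
#' @param mean,std Length-3 channel statistics.
#' @return A standardized `(size, size, 3)` array.
#' @export
eval_transform <- function(image, size = 224L, mean = IMAGENET_MEAN,
                           std = IMAGENET_STD) {
  if (length(dim(image)) != 3L) {
    stop_caspnet("eval_transform() expects an (H, W, C) image")
  }
  out <- bilinear_resize(image, size, size)
  for (ch in seq_len(dim(out)[3])) {
    out[, , ch] <- (out[, , ch] - mean[ch]) / std[ch]
  }
  out
}

# standardization without resizing (training path, post-augment)
standardize_image <- function(image, mean = IMAGENET_MEAN,
                              std = IMAGENET_STD) {
  for (ch in seq_len(dim(image)[3])) {
    image[, , ch] <- (image[, , ch] - mean[ch]) / std[ch]
  }
  image
}
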