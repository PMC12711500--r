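# Image and dataset I/O. Images are (H, W, 3) arrays with values in [0, 1].
# PNG and JPEG decode through the png/jpeg packages; BMP (the source
# dataset's native format) has no reader in the installed stack, so a
# minimal uncompressed 24-bit codec lives here.

IMG_EXTS <- c("bmp", "png", "jpg", "jpeg")

#' Read and write simple images
#'
#' `read_image()` decodes BMP, PNG or JPEG into an `(H, W, 3)` array in
#' `[0, 1]` (grayscale inputs are expanded to three channels, alpha is
#' dropped). `write_bmp()` writes an uncompressed 24-bit BMP;
#' `read_bmp()` reads it back exactly.
#'
#' @param path File path.
#' @param img `(H, W, 3)` array in `[0, 1]`.
#' @return `read_image()`/`read_bmp()`: an `(H, W, 3)` array;
#'   `write_bmp()`: `path`, invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(file_ext(path))
  img <- switch(ext,
                bmp = read_bmp(path),
                png = png::readPNG(path),
                jpg = ,
                jpeg = jpeg::readJPEG(path),
                stop_caspnet("unsupported image format: ", ext))
  if (is.null(dim(img)) || length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img) %||% length(img), 3L))
  } else if (dim(img)[3] == 1L) {
    img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' @rdname read_image
#' @export
write_bmp <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) {
    stop_caspnet("write_bmp() expects an (H, W, 3) array")
  }
  h <- d[1]
  w <- d[2]
  vals <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
  dim(vals) <- d
  # channel-fastest BGR, x within row, bottom-up rows
  bgr <- aperm(vals[, , c(3L, 2L, 1L), drop = FALSE], c(3, 2, 1))
  bgr <- bgr[, , h:1, drop = FALSE]
  rowbytes <- w * 3L
  pad <- (4L - rowbytes %% 4L) %% 4L
  m <- matrix(as.vector(bgr), rowbytes, h)
  if (pad > 0L) m <- rbind(m, matrix(0L, pad, h))
  payload <- as.raw(as.vector(m))
  img_size <- length(payload)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54L + img_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(54L, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")            # info header
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")             # no compression
  writeBin(as.integer(img_size), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

#' @rdname read_image
#' @export
read_bmp <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 54L || rawToChar(raw_all[1:2]) != "BM") {
    stop_caspnet("not a BMP file: ", path)
  }
  le32 <- function(i) {
    sum(as.integer(raw_all[i:(i + 3)]) * 256^(0:3))
  }
  le16 <- function(i) sum(as.integer(raw_all[i:(i + 1)]) * 256^(0:1))
  offset <- le32(11L)
  w <- le32(19L)
  h_raw <- le32(23L)
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- le16(29L)
  comp <- le32(31L)
  if (bpp != 24L || comp != 0L) {
    stop_caspnet("only uncompressed 24-bit BMP supported: ", path)
  }
  rowbytes <- w * 3L
  stride <- rowbytes + (4L - rowbytes %% 4L) %% 4L
  need <- offset + stride * h
  if (length(raw_all) < need) stop_caspnet("truncated BMP file: ", path)
  m <- matrix(as.integer(raw_all[(offset + 1L):(offset + stride * h)]),
              stride, h)[seq_len(rowbytes), , drop = FALSE]
  bgr <- array(m, c(3L, w, h))
  if (!top_down) bgr <- bgr[, , h:1, drop = FALSE]
  img <- aperm(bgr, c(3, 2, 1))[, , c(3L, 2L, 1L), drop = FALSE] / 255
  img
}

#' Load a class-per-directory image dataset
#'
#' Expects the standard image-folder layout: one sub-directory per class
#' containing BMP/PNG/JPEG files (the SIPAKMED layout). Class indices follow
#' the alphabetical order of the directory names. Files that fail to decode
#' are skipped with a warning reporting the total number of skips. A
#' sub-directory named `masks` is reserved for fixture ground truth and is
#' ignored.
#'
#' @param root Dataset root directory.
#' @param validate Decode every file at load time to drop corrupt images
#'   (default `TRUE`).
#' @return An object of class `image_set`: list with `items` (data.frame of
#'   `path`, `class_idx`, `class_name`), `class_names` and `counts`.
#' @export
load_dataset <- function(root, validate = TRUE) {
  if (!dir.exists(root)) stop_caspnet("dataset root does not exist: ", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = TRUE)
  dirs <- dirs[basename(dirs) != "masks"]
  dirs <- dirs[order(basename(dirs), method = "radix")]
  if (length(dirs) == 0L) {
    stop_caspnet("dataset root contains no class sub-directories: ", root)
  }
  items <- list()
  skipped <- 0L
  for (ci in seq_along(dirs)) {
    files <- list.files(dirs[ci], full.names = TRUE)
    files <- files[tolower(file_ext(files)) %in% IMG_EXTS]
    files <- files[order(basename(files), method = "radix")]
    ok <- logical(length(files))
    for (fi in seq_along(files)) {
      ok[fi] <- if (validate) {
        !inherits(try(read_image(files[fi]), silent = TRUE), "try-error")
      } else {
        TRUE
      }
    }
    skipped <- skipped + sum(!ok)
    files <- files[ok]
    if (length(files) == 0L) {
      stop_caspnet("no readable images in class directory: ",
                   basename(dirs[ci]))
    }
    items[[ci]] <- data.frame(path = files, class_idx = ci,
                              class_name = basename(dirs[ci]),
                              stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d unreadable image file(s)", skipped),
            call. = FALSE)
  }
  new_image_set(do.call(rbind, items), basename(dirs))
}

new_image_set <- function(items, class_names) {
  rownames(items) <- NULL
  counts <- vapply(seq_along(class_names), function(ci)
    sum(items$class_idx == ci), integer(1))
  names(counts) <- class_names
  structure(list(items = items, class_names = class_names, counts = counts),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image_set: %d images in %d classes\n",
              nrow(x$items), length(x$class_names)))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-26s %5d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' @export
length.image_set <- function(x) nrow(x$items)

# subset an image_set by item indices, keeping the class roster
subset_image_set <- function(set, idx) {
  new_image_set(set$items[idx, , drop = FALSE], set$class_names)
}

# Load all images of a set, eval-transformed to `side` pixels:
# returns (side, side, 3, N).
load_images <- function(set, side, mean = IMAGENET_MEAN, std = IMAGENET_STD) {
  n <- nrow(set$items)
  out <- array(0, c(side, side, 3L, n))
  for (i in seq_len(n)) {
    out[, , , i] <- eval_transform(read_image(set$items$path[i]), size = side,
                                   mean = mean, std = std)
  }
  out
}
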