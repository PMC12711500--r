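#' Synthetic cell-image fixture profiles
#'
#' Describes a class-conditional generator of single-cell images: each image
#' is background noise plus a cytoplasm ellipse, a nucleus ellipse and
#' chromatin-like speckles. Classes are separable through their
#' nucleus-to-cytoplasm (N:C) area-ratio ranges, nucleus eccentricity and
#' speckle density -- echoing the cytological cues (high N:C ratio,
#' hyperchromasia) that distinguish dysplastic cells. The geometry is
#' schematic, not a simulation of real Pap-smear optics.
#'
#' Presets:
#' \describe{
#'   \item{sipakmed}{Five classes with the benchmark's per-class counts
#'     (Dyskeratotic 813, Koilocytotic 825, Metaplastic 793, Parabasal 787,
#'     Superficial-Intermediate 813; 4049 total) and morphology ranges laid
#'     out per class.}
#'   \item{two_class}{`high_nc` vs `low_nc`, 32 images each, identical in
#'     every respect except the N:C ratio range -- the overfit/Grad-CAM
#'     test bed.}
#'   \item{tiny}{Like `sipakmed` but a handful of images per class.}
#' }
#'
#' @param preset One of `"sipakmed"`, `"two_class"`, `"tiny"`, or `NULL` to
#'   pass everything explicitly.
#' @param class_names Character vector of class names.
#' @param counts Per-class image counts.
#' @param size_range Image edge range in pixels (within `[32, 512]`).
#' @param ncr_range List (per class) of length-2 N:C area-ratio ranges, each
#'   inside (0, 1).
#' @param eccentricity_range List (per class) of nucleus eccentricity ranges.
#' @param speckle_density Per-class chromatin-speckle density (speckles per
#'   100 nucleus pixels).
#' @param halo Logical per class: render a koilocyte-like perinuclear halo.
#' @param noise_sd Background noise standard deviation.
#' @param per_class Overrides all counts with one number (convenience).
#' @param seed Integer seed; fixtures are byte-reproducible given the seed.
#' @return An object of class `fixture_profile`.
#' @export
fixture_profile <- function(preset = c("sipakmed", "two_class", "tiny"),
                            class_names = NULL, counts = NULL,
                            size_range = c(48L, 80L),
                            ncr_range = NULL, eccentricity_range = NULL,
                            speckle_density = NULL, halo = NULL,
                            noise_sd = 0.03, per_class = NULL, seed = 1L) {
  if (is.null(class_names)) {
    preset <- match.arg(preset)
    if (preset %in% c("sipakmed", "tiny")) {
      class_names <- c("Dyskeratotic", "Koilocytotic", "Metaplastic",
                       "Parabasal", "Superficial-Intermediate")
      counts <- counts %||% if (preset == "tiny") {
        rep(8L, 5L)
      } else {
        c(813L, 825L, 793L, 787L, 813L)
      }
      ncr_range <- ncr_range %||% list(c(0.40, 0.60), c(0.15, 0.30),
                                       c(0.25, 0.45), c(0.30, 0.50),
                                       c(0.05, 0.15))
      eccentricity_range <- eccentricity_range %||%
        list(c(0.3, 0.6), c(0.2, 0.5), c(0.1, 0.4), c(0.1, 0.3),
             c(0.1, 0.4))
      speckle_density <- speckle_density %||% c(2.5, 1.5, 1.0, 0.8, 0.5)
      halo <- halo %||% c(FALSE, TRUE, FALSE, FALSE, FALSE)
    } else {
      class_names <- c("high_nc", "low_nc")
      counts <- counts %||% c(32L, 32L)
      size_range <- c(64L, 64L)
      ncr_range <- ncr_range %||% list(c(0.45, 0.60), c(0.06, 0.12))
      eccentricity_range <- eccentricity_range %||%
        list(c(0.2, 0.4), c(0.2, 0.4))
      speckle_density <- speckle_density %||% c(1.0, 1.0)
      halo <- halo %||% c(FALSE, FALSE)
    }
  }
  k <- length(class_names)
  if (!is.null(per_class)) counts <- rep(check_count(per_class, "per_class",
                                                     min = 0), k)
  counts <- vapply(counts, check_count, integer(1), name = "counts", min = 0)
  if (length(counts) != k) stop_caspnet("one count per class required")
  if (any(size_range < 32) || any(size_range > 512)) {
    stop_caspnet("size_range must lie within [32, 512]")
  }
  for (r in ncr_range) {
    if (any(r <= 0) || any(r >= 1)) {
      stop_caspnet("N:C ratio ranges must lie inside (0, 1)")
    }
  }
  structure(list(class_names = class_names, counts = counts,
                 size_range = as.integer(size_range), ncr_range = ncr_range,
                 eccentricity_range = eccentricity_range,
                 speckle_density = speckle_density, halo = halo,
                 noise_sd = noise_sd,
                 seed = check_count(seed, "seed", min = 0)),
            class = "fixture_profile")
}

# soft-edged ellipse membership in [0, 1]; q is the ellipse quadratic form
soft_ellipse <- function(h, w, cy, cx, a, b, theta, edge = 0.15) {
  gy <- matrix(seq_len(h) - cy, h, w)
  gx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  u <- (gx * cos(theta) + gy * sin(theta)) / a
  v <- (-gx * sin(theta) + gy * cos(theta)) / b
  q <- u^2 + v^2
  list(alpha = pmin(pmax((1 + edge - q) / (2 * edge), 0), 1), q = q)
}

render_cell <- function(side, ncr, ecc, speckles, halo, noise_sd) {
  img <- array(rep(c(0.86, 0.80, 0.86), each = side * side),
               c(side, side, 3L))
  img <- img + array(rnorm(side * side * 3, 0, noise_sd), dim(img))
  # cytoplasm ellipse
  cyc <- side / 2 + runif(2, -side * 0.04, side * 0.04)
  cyto_area <- runif(1, 0.30, 0.45) * side^2
  asp <- runif(1, 0.8, 1.25)
  a_c <- sqrt(cyto_area * asp / pi)
  b_c <- cyto_area / (pi * a_c)
  th_c <- runif(1, 0, pi)
  cy <- soft_ellipse(side, side, cyc[1], cyc[2], a_c, b_c, th_c)
  cyto_col <- c(0.55, 0.72, 0.66) + runif(3, -0.05, 0.05)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - cy$alpha) + cyto_col[ch] * cy$alpha
  }
  # nucleus ellipse: area = ncr * cytoplasm area, eccentricity ecc
  nuc_area <- ncr * cyto_area
  ratio <- sqrt(1 - ecc^2)                 # b/a
  a_n <- sqrt(nuc_area / (pi * ratio))
  b_n <- a_n * ratio
  nc <- cyc + runif(2, -side * 0.03, side * 0.03)
  th_n <- runif(1, 0, pi)
  nu <- soft_ellipse(side, side, nc[1], nc[2], a_n, b_n, th_n)
  if (halo) {                              # perinuclear clearing
    ring <- pmin(pmax((2.6 - nu$q) / 1.2, 0), 1) * (1 - nu$alpha)
    halo_col <- c(0.80, 0.86, 0.84)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - 0.7 * ring) +
        halo_col[ch] * 0.7 * ring
    }
  }
  nuc_col <- c(0.36, 0.20, 0.46) + runif(3, -0.04, 0.04)
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - nu$alpha) + nuc_col[ch] * nu$alpha
  }
  mask <- nu$q <= 1
  # chromatin speckles: darker dots inside the nucleus
  n_spk <- round(speckles * sum(mask) / 100)
  if (n_spk > 0 && any(mask)) {
    cand <- which(mask, arr.ind = TRUE)
    pick <- cand[sample.int(nrow(cand), min(n_spk, nrow(cand))), ,
                 drop = FALSE]
    for (si in seq_len(nrow(pick))) {
      yy <- pick[si, 1] + (-1:1)
      xx <- pick[si, 2] + (-1:1)
      yy <- yy[yy >= 1 & yy <= side]
      xx <- xx[xx >= 1 & xx <= side]
      img[yy, xx, ] <- img[yy, xx, , drop = FALSE] * 0.55
    }
  }
  list(img = pmin(pmax(img, 0), 1), nucleus_mask = mask,
       cyto_mask = cy$q <= 1)
}

#' Generate a synthetic SIPAKMED-shaped fixture dataset
#'
#' Renders class-conditional cell images into `out_dir/<class>/*.bmp`,
#' writes binary nucleus masks to `out_dir/masks/<class>/*.png` and a
#' `manifest.csv` (path, class, mask, target and measured N:C ratio).
#' Generation is fully reproducible: each image derives its own RNG stream
#' from `(profile$seed, class, index)`, so re-running yields byte-identical
#' files.
#'
#' @param profile A [fixture_profile()].
#' @param out_dir Output directory (created if missing).
#' @param write_masks Logical; write the per-image nucleus masks.
#' @return The generated dataset as an `image_set` (invisible manifest
#'   attached as attribute `"manifest"`).
#' @export
generate_fixtures <- function(profile = fixture_profile(), out_dir,
                              write_masks = TRUE) {
  stopifnot(inherits(profile, "fixture_profile"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop_caspnet("output directory is not writable: ", out_dir)
  }
  rows <- list()
  for (ci in seq_along(profile$class_names)) {
    cname <- profile$class_names[ci]
    cdir <- file.path(out_dir, cname)
    dir.create(cdir, showWarnings = FALSE)
    mdir <- file.path(out_dir, "masks", cname)
    if (write_masks) dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(profile$counts[ci])) {
      res <- with_seed(derive_seed(profile$seed, ci, i), {
        side <- if (profile$size_range[1] == profile$size_range[2]) {
          profile$size_range[1]
        } else {
          sample(profile$size_range[1]:profile$size_range[2], 1L)
        }
        ncr <- runif(1, profile$ncr_range[[ci]][1],
                     profile$ncr_range[[ci]][2])
        ecc <- runif(1, profile$eccentricity_range[[ci]][1],
                     profile$eccentricity_range[[ci]][2])
        cell <- render_cell(side, ncr, ecc, profile$speckle_density[ci],
                            profile$halo[ci], profile$noise_sd)
        cell$ncr_target <- ncr
        cell
      })
      fname <- sprintf("%s_%04d.bmp", gsub("[^A-Za-z0-9]", "", cname), i)
      fpath <- file.path(cdir, fname)
      write_bmp(res$img, fpath)
      mpath <- NA_character_
      if (write_masks) {
        mpath <- file.path(mdir, sub("\\.bmp$", ".png", fname))
        png::writePNG(res$nucleus_mask * 1, mpath)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        path = fpath, class = cname, mask = mpath,
        ncr_target = res$ncr_target,
        ncr_measured = sum(res$nucleus_mask) / max(1, sum(res$cyto_mask)),
        size = dim(res$img)[1], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  set <- load_dataset(out_dir, validate = FALSE)
  attr(set, "manifest") <- manifest
  set
}
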