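#' Region-of-interest box
#'
#' 0-based, half-open pixel index box `[row_start, row_stop) x
#' [col_start, col_stop)`.
#'
#' @param row_start,row_stop,col_start,col_stop Integer bounds.
#' @return An object of class `oto_roi`.
#' @export
roi_box <- function(row_start, row_stop, col_start, col_stop) {
  b <- c(row_start = as.integer(row_start), row_stop = as.integer(row_stop),
         col_start = as.integer(col_start), col_stop = as.integer(col_stop))
  if (b["row_start"] < 0 || b["row_start"] >= b["row_stop"] ||
      b["col_start"] < 0 || b["col_start"] >= b["col_stop"])
    stop("invalid ROI box: need 0 <= start < stop", call. = FALSE)
  structure(as.list(b), class = "oto_roi")
}

#' Find the eardrum region of interest
#'
#' Binarizes the image by Rec. 601 luminance and returns the tightest
#' half-open box containing every pixel brighter than `threshold`: the first
#' and last foreground rows scanning top to bottom, and the first and last
#' foreground columns scanning left to right. This recovers the content box
#' of images framed by a near-black aperture margin.
#'
#' @param image An [oto_image()].
#' @param threshold Luminance threshold on the 0-255 scale (default 10;
#'   black JPEG borders are near zero but rarely exactly zero).
#' @return An [roi_box()].
#' @export
find_roi <- function(image, threshold = 10) {
  stopifnot(is_oto_image(image))
  fg <- luminance(image$pixels) > threshold
  rows <- which(rowSums(fg) > 0)
  cols <- which(colSums(fg) > 0)
  if (length(rows) == 0L)
    stop("no foreground: every pixel is at or below the threshold", call. = FALSE)
  roi_box(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols))
}

#' Crop an image to a box
#'
#' @param image An [oto_image()].
#' @param box An [roi_box()] within the image bounds.
#' @return An [oto_image()] of shape `(row_stop - row_start, col_stop -
#'   col_start, 3)`; pixels copied unchanged, label and id preserved.
#' @export
crop_roi <- function(image, box) {
  stopifnot(is_oto_image(image), inherits(box, "oto_roi"))
  d <- dim(image$pixels)
  if (box$row_stop > d[1] || box$col_stop > d[2])
    stop("ROI box exceeds image bounds", call. = FALSE)
  px <- image$pixels[(box$row_start + 1):box$row_stop,
                     (box$col_start + 1):box$col_stop, , drop = FALSE]
  oto_image(px, image$label, image$id)
}

#' Zero out the burned-in timestamp region
#'
#' Otoscope captures carry the acquisition time burned into a fixed
#' bottom-right region. Because its location is fixed, the region is simply
#' excluded: pixels in the bottom `region_height_frac` of rows and right
#' `region_width_frac` of columns are set to 0 in all channels; everything
#' else is untouched, so image geometry is preserved. Intended to run after
#' [crop_roi()].
#'
#' @param image An [oto_image()].
#' @param region_height_frac,region_width_frac Fractions in `(0, 0.5]`;
#'   defaults cover the bottom 8% x right 25%.
#' @return The image with the region zero-filled. Idempotent.
#' @export
remove_timestamp <- function(image, region_height_frac = 0.08,
                             region_width_frac = 0.25) {
  stopifnot(is_oto_image(image))
  if (region_height_frac <= 0 || region_height_frac > 0.5 ||
      region_width_frac <= 0 || region_width_frac > 0.5)
    stop("timestamp region fractions must lie in (0, 0.5]", call. = FALSE)
  d <- dim(image$pixels)
  nr <- max(1L, ceiling(region_height_frac * d[1]))
  nc <- max(1L, ceiling(region_width_frac * d[2]))
  px <- image$pixels
  px[(d[1] - nr + 1):d[1], (d[2] - nc + 1):d[2], ] <- 0
  oto_image(px, image$label, image$id)
}

#' Data-augmentation specification
#'
#' Random affine transforms used to balance classes during training:
#' horizontal/vertical reflection (each applied with probability 1/2 when
#' enabled), rotation uniform over the full circle, isotropic scaling in
#' `[0.7, 2]`, horizontal and vertical shear in `[0, 45]` degrees, and
#' translation in `[-30, 30]` pixels along both axes.
#'
#' @param reflect_horizontal,reflect_vertical Allow the respective flip.
#' @param rotate_min,rotate_max Rotation range, degrees.
#' @param scale_min,scale_max Isotropic scale factor range.
#' @param shear_min,shear_max Shear range, degrees, within `[0, 45]`.
#' @param translate_min,translate_max Translation range, pixels, within
#'   `[-30, 30]`.
#' @param seed Integer seed for the parameter draws.
#' @return An object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(reflect_horizontal = TRUE, reflect_vertical = TRUE,
                              rotate_min = 0, rotate_max = 360,
                              scale_min = 0.7, scale_max = 2,
                              shear_min = 0, shear_max = 45,
                              translate_min = -30, translate_max = 30,
                              seed = 1) {
  if (scale_min > scale_max || scale_min <= 0)
    stop("need 0 < scale_min <= scale_max", call. = FALSE)
  if (shear_min < 0 || shear_max > 45 || shear_min > shear_max)
    stop("shear range must lie within [0, 45] degrees", call. = FALSE)
  if (translate_min < -30 || translate_max > 30 || translate_min > translate_max)
    stop("translation range must lie within [-30, 30] pixels", call. = FALSE)
  structure(
    list(reflect_horizontal = isTRUE(reflect_horizontal),
         reflect_vertical = isTRUE(reflect_vertical),
         rotate_min = rotate_min, rotate_max = rotate_max,
         scale_min = scale_min, scale_max = scale_max,
         shear_min = shear_min, shear_max = shear_max,
         translate_min = translate_min, translate_max = translate_max,
         seed = as.integer(seed)),
    class = "augmentation_spec"
  )
}

draw_one_transform <- function(spec) {
  list(
    flip_h = spec$reflect_horizontal && runif(1) < 0.5,
    flip_v = spec$reflect_vertical && runif(1) < 0.5,
    rotation = runif(1, spec$rotate_min, spec$rotate_max),
    scale = runif(1, spec$scale_min, spec$scale_max),
    shear_h = runif(1, spec$shear_min, spec$shear_max),
    shear_v = runif(1, spec$shear_min, spec$shear_max),
    translate_row = runif(1, spec$translate_min, spec$translate_max),
    translate_col = runif(1, spec$translate_min, spec$translate_max)
  )
}

#' Sample augmentation transform parameters
#'
#' Draws `n` transform parameter sets from the spec's ranges, as used by
#' [augment()]. Exposed so the sampled distributions can be inspected.
#'
#' @param spec An [augmentation_spec()].
#' @param n Number of draws.
#' @param seed Seed (defaults to the spec's).
#' @return Data frame with one row per draw.
#' @export
draw_augment_params <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "augmentation_spec"))
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i)
      as.data.frame(draw_one_transform(spec))))
  })
}

is_identity_transform <- function(p) {
  !p$flip_h && !p$flip_v &&
    p$rotation %% 360 == 0 && p$scale == 1 &&
    p$shear_h == 0 && p$shear_v == 0 &&
    p$translate_row == 0 && p$translate_col == 0
}

## 2x2 linear part of the affine transform in (row, col) coordinates,
## row-vector convention: applied as p %*% A. Order: flip, scale, shear,
## rotation.
transform_matrix <- function(p) {
  flip <- diag(c(if (p$flip_v) -1 else 1, if (p$flip_h) -1 else 1))
  sc <- diag(c(p$scale, p$scale))
  sh <- matrix(c(1, tanpi(p$shear_v / 180), tanpi(p$shear_h / 180), 1), 2, 2)
  th <- p$rotation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  flip %*% sc %*% sh %*% rot
}

apply_affine <- function(pixels, p) {
  d <- dim(pixels)
  A <- transform_matrix(p)
  centre <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  shift <- centre - as.vector(centre %*% A) +
    c(p$translate_row, p$translate_col)
  m <- rbind(A, shift)
  out <- array(0, dim = d)
  for (ch in seq_len(d[3]))
    out[, , ch] <- EBImage::affine(pixels[, , ch], m, filter = "bilinear",
                                   bg.col = 0)
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Apply one random augmentation transform
#'
#' Draws a single affine transform from the spec's ranges and applies it with
#' bilinear interpolation; pixels exposed by the transform are filled with
#' black. The output has the same shape, label and id as the input, and the
#' same seed always yields the same output. A degenerate spec (no flips,
#' rotation 0-0, scale 1-1, shear 0-0, translation 0-0) is the identity.
#'
#' @param image An [oto_image()].
#' @param spec An [augmentation_spec()].
#' @param seed Seed for the draw (defaults to the spec's).
#' @return Transformed [oto_image()].
#' @export
augment <- function(image, spec, seed = spec$seed) {
  stopifnot(is_oto_image(image), inherits(spec, "augmentation_spec"))
  p <- withr::with_seed(seed, draw_one_transform(spec))
  if (is_identity_transform(p)) return(image)
  oto_image(apply_affine(image$pixels, p), image$label, image$id)
}

#' Balance class counts by augmented resampling
#'
#' Brings every class up to the size of the largest class by randomly
#' resampling minority-class images (with replacement) and appending one
#' augmented copy per draw. Majority-class images are passed through
#' unchanged; originals always precede additions in the output. Augmented
#' copies get ids `<original id>_aug<n>`.
#'
#' @param images List of [oto_image()] with at least one image per class
#'   present.
#' @param spec An [augmentation_spec()].
#' @param seed Seed controlling both the resampling and the per-copy
#'   transforms (defaults to the spec's).
#' @return List of [oto_image()] with equal class counts.
#' @export
balance_classes <- function(images, spec, seed = spec$seed) {
  stopifnot(length(images) > 0, inherits(spec, "augmentation_spec"))
  labels <- image_labels(images)
  counts <- table(labels)
  if (any(counts == 0)) stop("empty class", call. = FALSE)
  target <- max(counts)
  additions <- list()
  n_aug <- 0L
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      deficit <- target - counts[[cl]]
      if (deficit == 0) next
      pool <- which(labels == cl)
      picks <- pool[sample.int(length(pool), deficit, replace = TRUE)]
      for (ix in picks) {
        n_aug <- n_aug + 1L
        src <- images[[ix]]
        copy <- augment(src, spec, seed = seed + n_aug)
        copy$id <- paste0(src$id, "_aug", n_aug)
        additions[[n_aug]] <- copy
      }
    }
  })
  c(images, additions)
}

#' Variance-of-Laplacian blur score
#'
#' A simple focus measure: the population variance of the 3x3 Laplacian of
#' the luminance image. Lower values indicate blurrier images. Provided for
#' optional quality screening; nothing in the pipeline applies a threshold
#' by default.
#'
#' @param image An [oto_image()].
#' @return Non-negative scalar.
#' @export
blur_score <- function(image) {
  stopifnot(is_oto_image(image))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  r <- EBImage::filter2(luminance(image$pixels) / 255, lap,
                        boundary = "replicate")
  mean((r - mean(r))^2)
}
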