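#' Specification for the synthetic otoscopy-image generator
#'
#' Describes a deterministic toy dataset with the structural features the
#' retrieval pipeline assumes: three classes whose colour distributions are
#' separable to a tunable degree, a pure-black circular-aperture style margin,
#' and an optional burned-in timestamp block near the bottom-right of the
#' region of interest.
#'
#' `separability` scales every class-discriminating cue at once: at 0 the
#' three classes share one colour distribution and the tube marker has zero
#' contrast (classes are statistically identical); at 1 the per-class hue
#' ranges are disjoint and the tube marker is fully visible.
#'
#' @param n_per_class Positive integer, images generated for each class.
#' @param height,width Image size in pixels (at least 16 recommended so the
#'   timestamp block fits its default removal region).
#' @param separability Real in `[0, 1]`.
#' @param margin_fraction Real in `[0, 0.4]`; black border thickness as a
#'   fraction of the smaller image dimension.
#' @param timestamp Logical; burn a solid white block into the bottom-right
#'   of the inner (non-margin) region.
#' @param blur_sigma Optional Gaussian blur (pixels) applied to the finished
#'   image, for quality-sensitivity experiments. 0 disables.
#' @param seed Integer seed; the same spec (including seed) always yields a
#'   bit-identical image set.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class, height = 64, width = 64, separability = 1,
                       margin_fraction = 0.1, timestamp = TRUE,
                       blur_sigma = 0, seed = 1) {
  if (length(n_per_class) != 1L || is.na(n_per_class) || n_per_class < 1 ||
      n_per_class != round(n_per_class))
    stop("`n_per_class` must be a positive integer", call. = FALSE)
  if (separability < 0 || separability > 1)
    stop("`separability` must lie in [0, 1]", call. = FALSE)
  if (margin_fraction < 0 || margin_fraction > 0.4)
    stop("`margin_fraction` must lie in [0, 0.4]", call. = FALSE)
  if (height < 8 || width < 8)
    stop("images smaller than 8x8 are not supported", call. = FALSE)
  structure(
    list(n_per_class = as.integer(n_per_class), height = as.integer(height),
         width = as.integer(width), separability = separability,
         margin_fraction = margin_fraction, timestamp = isTRUE(timestamp),
         blur_sigma = blur_sigma, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

## Class palette. Hue centres move away from the shared base hue linearly in
## `separability`; per-image jitter is truncated at +/-0.03 so that at
## separability 1 the three hue ranges are disjoint.
SYNTH_BASE_HUE <- 0.02
SYNTH_HUE_DELTA <- c(effusion = 0.06, normal = -0.055, tube = -0.15)
SYNTH_HUE_JITTER_SD <- 0.012

wrap_hue <- function(h) h - floor(h)

## Smooth random field: coarse Gaussian grid bilinearly upsampled.
smooth_field <- function(h, w, grid = 6) {
  g <- matrix(rnorm(grid * grid), grid, grid)
  EBImage::resize(g, w = h, h = w)
}

## Geometry of the timestamp block inside an inner box of size ih x iw.
## Sized so that after cropping to the inner box the block sits inside the
## default removal region (bottom 8% of rows x right 25% of columns).
timestamp_box <- function(ih, iw) {
  bh <- max(1L, as.integer(round(0.04 * ih)))
  bw <- max(2L, as.integer(round(0.15 * iw)))
  gr <- max(1L, as.integer(round(0.015 * ih)))
  gc <- max(1L, as.integer(round(0.015 * iw)))
  ## 0-based half-open, relative to the inner box
  c(row_start = ih - gr - bh, row_stop = ih - gr,
    col_start = iw - gc - bw, col_stop = iw - gc)
}

synth_one_image <- function(spec, class_idx, id) {
  h <- spec$height; w <- spec$width; sep <- spec$separability
  m <- floor(spec$margin_fraction * min(h, w))
  ih <- h - 2L * m; iw <- w - 2L * m
  cls <- OTO_CLASSES[class_idx]

  ## Per-image appearance parameters
  jit <- max(-0.03, min(0.03, rnorm(1, 0, SYNTH_HUE_JITTER_SD)))
  hue0 <- wrap_hue(SYNTH_BASE_HUE + sep * SYNTH_HUE_DELTA[[cls]] + jit)
  sat0 <- runif(1, 0.45, 0.6)
  val0 <- runif(1, 160, 195)

  ## Elliptical "drum" inside the inner box
  cy <- (ih + 1) / 2 + runif(1, -0.03, 0.03) * ih
  cx <- (iw + 1) / 2 + runif(1, -0.03, 0.03) * iw
  ay <- 0.40 * ih * runif(1, 0.95, 1.05)
  ax <- 0.40 * iw * runif(1, 0.95, 1.05)

  rows <- matrix(seq_len(ih), ih, iw)
  cols <- matrix(seq_len(iw), ih, iw, byrow = TRUE)
  rr <- ((rows - cy) / ay)^2 + ((cols - cx) / ax)^2
  inside <- rr <= 1

  hue_f <- smooth_field(ih, iw) * 0.01
  val_f <- smooth_field(ih, iw) * 18
  tex_f <- smooth_field(ih, iw) * 6

  ## Dim desaturated background just above the binarization threshold range
  bg <- pmin(70, pmax(25, 45 + tex_f + rnorm(ih * iw, 0, 2)))
  inner <- array(0, dim = c(ih, iw, 3))
  for (ch in 1:3) inner[, , ch] <- bg

  ## Drum colouring: radial brightness falloff plus smooth hue/value fields
  hpx <- wrap_hue(hue0 + hue_f[inside])
  vpx <- pmin(245, pmax(110, val0 + val_f[inside] - 55 * rr[inside]))
  spx <- pmin(0.85, pmax(0.2, sat0 + hue_f[inside] * 4))
  rgb01 <- hsv2rgb_matrix(hpx, spx, vpx / 255)
  for (ch in 1:3) {
    plane <- inner[, , ch]
    plane[inside] <- rgb01[ch, ] * 255
    inner[, , ch] <- plane
  }

  ## Tube marker: small bright ellipse, contrast proportional to separability
  if (cls == "tube" && sep > 0) {
    ang <- runif(1, 0, 2 * pi)
    tcy <- cy + 0.25 * ay * sin(ang); tcx <- cx + 0.25 * ax * cos(ang)
    tay <- 0.18 * ay; tax <- 0.18 * ax
    tin <- ((rows - tcy) / tay)^2 + ((cols - tcx) / tax)^2 <= 1
    for (ch in 1:3) {
      plane <- inner[, , ch]
      plane[tin] <- (1 - sep) * plane[tin] + sep * 250
      inner[, , ch] <- plane
    }
  }

  tb <- NULL
  if (spec$timestamp) {
    tb <- timestamp_box(ih, iw)
    inner[(tb["row_start"] + 1):tb["row_stop"],
          (tb["col_start"] + 1):tb["col_stop"], ] <- 255
  }

  px <- array(0, dim = c(h, w, 3))
  px[(m + 1):(h - m), (m + 1):(w - m), ] <- inner

  if (spec$blur_sigma > 0) {
    for (ch in 1:3)
      px[, , ch] <- EBImage::gblur(px[, , ch], sigma = spec$blur_sigma)
    px[px < 0] <- 0; px[px > 255] <- 255
    ## keep the margin contract exact under blur
    if (m > 0) {
      keep <- array(0, dim = c(h, w, 3))
      keep[(m + 1):(h - m), (m + 1):(w - m), ] <- px[(m + 1):(h - m), (m + 1):(w - m), ]
      px <- keep
    }
  }

  img <- oto_image(round(px), cls, id)
  attr(img, "roi") <- c(row_start = m, row_stop = h - m,
                        col_start = m, col_stop = w - m)
  if (!is.null(tb))
    attr(img, "timestamp_box") <- tb + c(m, m, m, m)
  img
}

## Vectorized HSV -> RGB (h, s in [0,1], v in [0,1]); returns 3 x n matrix.
hsv2rgb_matrix <- function(h, s, v) {
  col2rgb(hsv(h = h, s = s, v = v)) / 255
}

#' Generate a synthetic labelled image set
#'
#' Produces `3 * n_per_class` images (classes effusion, normal, tube, in
#' blocks, in that order). Each image carries attributes `roi` (the
#' ground-truth inner box as a 0-based half-open `row_start, row_stop,
#' col_start, col_stop` vector) and, when `timestamp = TRUE`, `timestamp_box`
#' in full-image coordinates, so preprocessing can be tested exactly.
#'
#' @param spec A [synth_spec()].
#' @return List of [oto_image()] objects.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    out <- vector("list", 3L * spec$n_per_class)
    n <- 0L
    for (ci in 1:3) {
      for (i in seq_len(spec$n_per_class)) {
        n <- n + 1L
        id <- sprintf("%s_%03d", OTO_CLASSES[ci], i)
        out[[n]] <- synth_one_image(spec, ci, id)
      }
    }
    out
  })
}
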