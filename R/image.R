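#' Labelled RGB image
#'
#' The unit of all pipeline input: an 8-bit RGB pixel raster together with a
#' diagnostic class label and a stable identifier. Pixels are stored as a
#' `height x width x 3` numeric array with values in `[0, 255]`.
#'
#' @param pixels Numeric array `h x w x 3`, values in `[0, 255]`.
#' @param label Class label, one of [oto_classes()] (other labels are allowed
#'   but the shipped backbones only know the canonical three).
#' @param id Unique identifier string.
#' @return An object of class `oto_image`.
#' @export
oto_image <- function(pixels, label, id) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("`id` must be a non-empty string", call. = FALSE)
  structure(
    list(pixels = pixels, label = as.character(label), id = id),
    class = "oto_image"
  )
}

#' @export
print.oto_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<oto_image> %s  %dx%d  label=%s\n", x$id, d[1], d[2], x$label))
  invisible(x)
}

#' @export
dim.oto_image <- function(x) dim(x$pixels)

is_oto_image <- function(x) inherits(x, "oto_image")

## Rec. 601 luma of an h x w x 3 array (0..255) -> h x w matrix (0..255).
luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Labels and ids of an image list
#'
#' @param images List of [oto_image()] objects.
#' @return Character vector, one entry per image.
#' @export
image_labels <- function(images) vapply(images, function(im) im$label, character(1))

#' @rdname image_labels
#' @export
image_ids <- function(images) vapply(images, function(im) im$id, character(1))

## EBImage stores matrices with dim1 = x; our rasters use dim1 = rows.
## Channel-wise helpers keep the row/column convention explicit.
resize_raster <- function(pixels, out_h, out_w) {
  out <- array(0, dim = c(out_h, out_w, dim(pixels)[3]))
  for (ch in seq_len(dim(pixels)[3]))
    out[, , ch] <- EBImage::resize(pixels[, , ch], w = out_h, h = out_w)
  out
}

#' Write images and a manifest to disk
#'
#' Writes each image as `<id>.png` under `dir` and a `manifest.csv` with
#' columns `id`, `path`, `label`, `split` (empty at generation time).
#'
#' @param images List of [oto_image()] objects.
#' @param dir Output directory (created if missing).
#' @param split Optional character vector of split assignments, recycled.
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(images, dir, split = "") {
  stopifnot(all(vapply(images, is_oto_image, logical(1))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(images))
  for (i in seq_along(images)) {
    paths[i] <- file.path(dir, paste0(images[[i]]$id, ".png"))
    png::writePNG(images[[i]]$pixels / 255, target = paths[i])
  }
  manifest <- data.frame(
    id = image_ids(images),
    path = paths,
    label = image_labels(images),
    split = rep_len(split, length(images)),
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset back from a manifest
#'
#' @param manifest Path to a manifest CSV (as written by [write_dataset()])
#'   or a data frame with columns `id`, `path`, `label`.
#' @return List of [oto_image()] objects in manifest order.
#' @export
read_dataset <- function(manifest) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(manifest$path[i])
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3L))
    if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
    oto_image(round(px * 255), manifest$label[i], manifest$id[i])
  })
}
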