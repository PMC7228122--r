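#' Preprocess a dataset on disk
#'
#' For each image in the manifest: find the region of interest, crop to it,
#' and zero the timestamp region; write the result and a new manifest.
#'
#' @param manifest Path to a manifest CSV (see [write_dataset()]).
#' @param out_dir Output directory.
#' @param threshold Luminance threshold for [find_roi()].
#' @param region_height_frac,region_width_frac Passed to
#'   [remove_timestamp()].
#' @return Invisibly, the new manifest data frame.
#' @export
preprocess_dataset <- function(manifest, out_dir, threshold = 10,
                               region_height_frac = 0.08,
                               region_width_frac = 0.25) {
  images <- read_dataset(manifest)
  out <- lapply(images, function(im) {
    im <- crop_roi(im, find_roi(im, threshold))
    remove_timestamp(im, region_height_frac, region_width_frac)
  })
  write_dataset(out, out_dir)
}

#' Train a backbone and index a dataset
#'
#' Convenience wrapper over the offline stages: stratified train/validation
#' split, class balancing, head fine-tuning, and lookup-table construction
#' from the training images.
#'
#' @param images List of [oto_image()].
#' @param backbone An `oto_backbone` (default: a fresh [tiny_backbone()]).
#' @param train_cfg A [train_config()].
#' @param augmentation An [augmentation_spec()] used for balancing.
#' @param val_frac Fraction held out for validation, stratified.
#' @param use_bias,normalize Passed to [build_lookup()].
#' @param seed Seed for the split and balancing.
#' @return List with `backbone` (fine-tuned), `table` (an `oto_lookup` over
#'   the training images), `train_ids`, `val_ids`.
#' @export
train_and_index <- function(images, backbone = tiny_backbone(seed = seed),
                            train_cfg = train_config(),
                            augmentation = augmentation_spec(),
                            val_frac = 0.3, use_bias = TRUE,
                            normalize = FALSE, seed = 1) {
  labels <- image_labels(images)
  val <- integer(0)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      val <- c(val, ix[sample.int(length(ix), max(1, round(val_frac * length(ix))))])
    }
  })
  train <- setdiff(seq_along(images), val)
  aug <- augmentation; aug$seed <- as.integer(seed)
  balanced <- balance_classes(images[train], aug)
  backbone <- fine_tune(backbone, balanced, images[val], train_cfg)
  pw <- get_projection(backbone)
  feats <- extract_feature_matrix(backbone, images[train])
  table <- build_lookup(feats, labels[train], pw, use_bias = use_bias,
                        normalize = normalize)
  list(backbone = backbone, table = table,
       train_ids = image_ids(images[train]),
       val_ids = image_ids(images[val]))
}

#' Query one image against an indexed database
#'
#' Online stage: extract the query's pooled features, project them into
#' class-score space, and retrieve the `k` nearest lookup rows.
#'
#' @param image An [oto_image()].
#' @param backbone The fine-tuned backbone used to build the table.
#' @param table An `oto_lookup`.
#' @param k Retrieval depth.
#' @param metric `"chebyshev"` or `"cosine"`.
#' @param use_bias Must match how the table was built.
#' @return An `oto_query_result`.
#' @export
query_image <- function(image, backbone, table, k = 5,
                        metric = c("chebyshev", "cosine"), use_bias = TRUE) {
  metric <- match.arg(metric)
  f <- extract_features(backbone, image)
  q <- project(f, get_projection(backbone), use_bias = use_bias)
  retrieve(q, table, k, metric, query_id = image$id)
}
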