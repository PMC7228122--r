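# Shared fixtures. Generation is seeded, so every test run sees identical
# data; small sets are cached per test session to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

## 30 images/class, fully separable, 64x64 -- the workhorse dataset.
sep1_images <- function() {
  cached("sep1", generate_dataset(synth_spec(n_per_class = 30, separability = 1,
                                             seed = 101)))
}

## A trained backbone on a 30/9 per-class split of sep1_images().
trained_backbone <- function() {
  cached("trained_bb", {
    imgs <- sep1_images()
    labels <- image_labels(imgs)
    tr <- unlist(lapply(oto_classes(), function(cl) which(labels == cl)[1:21]))
    va <- setdiff(seq_along(imgs), tr)
    fine_tune(tiny_backbone(seed = 7), imgs[tr], imgs[va],
              train_config(epochs = 40, seed = 7))
  })
}

## Tiny flat-colour image helper: constant or per-pixel custom raster.
flat_image <- function(r, g, b, h = 8, w = 8, label = "normal", id = "flat") {
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  oto_image(px, label, id)
}

raster_image <- function(px, label = "normal", id = "img") {
  oto_image(px, label, id)
}

## Mean-RGB nearest-class-mean classifier accuracy (leave-one-in, as a
## simple separability probe).
nearest_class_mean_accuracy <- function(images) {
  labels <- image_labels(images)
  feats <- t(vapply(images, function(im) apply(im$pixels, 3, mean), numeric(3)))
  centroids <- rowsum(feats, labels) / as.vector(table(labels)[sort(unique(labels))])
  pred <- rownames(centroids)[apply(feats, 1, function(f)
    which.min(colSums((t(centroids) - f)^2)))]
  mean(pred == labels)
}
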