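#' Tiny CPU-trainable CNN backbone
#'
#' The retrieval method is backbone-agnostic: any classification CNN with a
#' global average-pooling feature layer followed by a fully-connected layer
#' fits the contract (the original large-scale instantiation is
#' Inception-ResNet-v2, input 299x299, 1536 pooled features, with all but the
#' last few of its 825 layers frozen). This constructor builds the small
#' instantiation shipped with the package: three 3x3 convolution blocks
#' (ReLU + 2x2 max pooling), global average pooling, and a fully-connected
#' classification head. The convolutional layers are initialized from the
#' seed and frozen, mirroring transfer learning at desk scale; only the head
#' is trainable.
#'
#' @param input_size Integer `(height, width)` the network resizes inputs to.
#'   Must be divisible by 8.
#' @param channels Output channels of the three convolution blocks; the last
#'   entry is the pooled feature dimension `F`.
#' @param num_classes Number of classes `C`.
#' @param class_order Class labels in score-column order.
#' @param seed Seed for the (frozen) weight initialization.
#' @return An object of class `oto_backbone`.
#' @export
tiny_backbone <- function(input_size = c(32, 32), channels = c(8, 12, 16),
                          num_classes = 3, class_order = oto_classes(),
                          seed = 1) {
  stopifnot(length(input_size) == 2, all(input_size %% 8 == 0),
            length(channels) == 3, num_classes >= 2,
            length(class_order) == num_classes)
  withr::with_seed(as.integer(seed), {
    in_ch <- c(3L, channels[1], channels[2])
    convs <- lapply(1:3, function(i) {
      fan_in <- 9 * in_ch[i]
      list(W = array(rnorm(9 * in_ch[i] * channels[i], 0, sqrt(2 / fan_in)),
                     dim = c(3, 3, in_ch[i], channels[i])),
           b = numeric(channels[i]))
    })
    fc <- list(W = matrix(rnorm(channels[3] * num_classes, 0, 0.01),
                          channels[3], num_classes),
               b = numeric(num_classes))
  })
  structure(
    list(input_size = as.integer(input_size), channels = as.integer(channels),
         feature_dim = as.integer(channels[3]),
         num_classes = as.integer(num_classes),
         class_order = as.character(class_order),
         conv = convs, fc = fc,
         frozen_layer_count = 3L, total_layer_count = 4L,
         seed = as.integer(seed), history = NULL),
    class = "oto_backbone"
  )
}

#' @export
print.oto_backbone <- function(x, ...) {
  cat(sprintf(
    "<oto_backbone> input %dx%d, channels %s, F=%d, C=%d (%d of %d layers frozen)\n",
    x$input_size[1], x$input_size[2], paste(x$channels, collapse = "-"),
    x$feature_dim, x$num_classes, x$frozen_layer_count, x$total_layer_count))
  invisible(x)
}

## -- forward pass internals ---------------------------------------------

## 'same' 3x3 convolution via im2col. x: H x W x Cin array. Returns H x W x Cout.
conv3x3 <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; cin <- d[3]; cout <- dim(W)[4]
  pad <- array(0, dim = c(H + 2, Wd + 2, cin))
  pad[2:(H + 1), 2:(Wd + 1), ] <- x
  blocks <- vector("list", 9L)
  wrows <- vector("list", 9L)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1L
    patch <- pad[(di + 1):(di + H), (dj + 1):(dj + Wd), , drop = FALSE]
    blocks[[k]] <- matrix(patch, H * Wd, cin)
    wrows[[k]] <- matrix(W[di + 1, dj + 1, , ], cin, cout)
  }
  out <- do.call(cbind, blocks) %*% do.call(rbind, wrows)
  out <- sweep(out, 2, b, "+")
  array(out, dim = c(H, Wd, cout))
}

relu <- function(x) { x[x < 0] <- 0; x }

maxpool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1], by = 2); i2 <- seq(2, d[1], by = 2)
  j1 <- seq(1, d[2], by = 2); j2 <- seq(2, d[2], by = 2)
  pmax(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
       x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
}

## Resize to the backbone's input size, scale to [-0.5, 0.5], run the frozen
## convolutional stack, and global-average-pool to a length-F vector.
backbone_pooled_features <- function(backbone, image) {
  x <- resize_raster(image$pixels, backbone$input_size[1],
                     backbone$input_size[2]) / 255 - 0.5
  for (i in 1:3) {
    x <- maxpool2(relu(conv3x3(x, backbone$conv[[i]]$W, backbone$conv[[i]]$b)))
  }
  apply(x, 3, mean)
}

#' Extract the pooled feature vector of an image
#'
#' Runs the backbone forward up to and including global average pooling.
#' Deterministic given the backbone state. The returned vector carries the
#' image id as attribute `id`.
#'
#' @param backbone An [tiny_backbone()] (or any `oto_backbone`).
#' @param image An [oto_image()] of any size; it is resized to the
#'   backbone's input size with bilinear interpolation.
#' @return Numeric vector of length `backbone$feature_dim`.
#' @export
extract_features <- function(backbone, image) {
  stopifnot(inherits(backbone, "oto_backbone"), is_oto_image(image))
  f <- backbone_pooled_features(backbone, image)
  attr(f, "id") <- image$id
  f
}

#' Extract pooled features for a list of images
#'
#' @param backbone An `oto_backbone`.
#' @param images List of [oto_image()].
#' @return `N x F` matrix with image ids as row names.
#' @export
extract_feature_matrix <- function(backbone, images) {
  m <- t(vapply(images, function(im) backbone_pooled_features(backbone, im),
                numeric(backbone$feature_dim)))
  rownames(m) <- image_ids(images)
  m
}

#' Class scores of an image (pre-softmax)
#'
#' Full forward pass: pooled features projected through the fully-connected
#' layer. Equals `project(extract_features(backbone, image),
#' get_projection(backbone))` by construction.
#'
#' @inheritParams extract_features
#' @return Numeric length-`C` vector named by `class_order`.
#' @export
backbone_scores <- function(backbone, image) {
  f <- backbone_pooled_features(backbone, image)
  setNames(as.vector(f %*% backbone$fc$W + backbone$fc$b),
           backbone$class_order)
}

#' Training configuration for fine-tuning
#'
#' @param epochs Non-negative integer; 0 is an exact no-op.
#' @param batch_size Positive integer mini-batch size.
#' @param learning_rate Positive step size for the softmax-regression SGD on
#'   the fully-connected head.
#' @param seed Seed for initialization shuffling and batching.
#' @param retrain_layer_count Number of trailing parameterized layers to
#'   retrain. The tiny backbone has exactly one trainable layer (the
#'   fully-connected head; the softmax and classification-output layers that
#'   follow it carry no parameters), so only 1 is accepted here. Larger
#'   backbones may support more.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 40, batch_size = 16, learning_rate = 0.5,
                         seed = 1, retrain_layer_count = 1) {
  stopifnot(epochs >= 0, epochs == round(epochs), batch_size >= 1,
            learning_rate > 0, retrain_layer_count >= 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed),
         retrain_layer_count = as.integer(retrain_layer_count)),
    class = "train_config"
  )
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fine-tune the backbone on labelled images
#'
#' Transfer-learning step: the frozen convolutional layers are untouched
#' (bit-identical before and after); only the fully-connected head is
#' retrained, by mini-batch gradient descent on the softmax cross-entropy.
#' Because the convolutional stack is frozen, pooled features are computed
#' once per image and the head is fit on them directly. Per-epoch validation
#' classification accuracy is recorded in the returned backbone's `history`.
#'
#' @param backbone An `oto_backbone`.
#' @param train,val Non-empty lists of [oto_image()] whose labels all occur
#'   in `backbone$class_order`.
#' @param cfg A [train_config()].
#' @return The updated backbone. With `epochs = 0` the input is returned
#'   identically.
#' @export
fine_tune <- function(backbone, train, val, cfg = train_config()) {
  stopifnot(inherits(backbone, "oto_backbone"), inherits(cfg, "train_config"))
  if (length(train) == 0 || length(val) == 0)
    stop("empty training or validation split", call. = FALSE)
  if (cfg$retrain_layer_count > 1)
    stop("the tiny backbone has a single trainable layer (its fully-connected head)",
         call. = FALSE)
  lab_tr <- image_labels(train); lab_va <- image_labels(val)
  unknown <- setdiff(unique(c(lab_tr, lab_va)), backbone$class_order)
  if (length(unknown) > 0)
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (cfg$epochs == 0L) return(backbone)

  X <- extract_feature_matrix(backbone, train)
  Xv <- extract_feature_matrix(backbone, val)
  yi <- match(lab_tr, backbone$class_order)
  Y <- matrix(0, nrow(X), backbone$num_classes)
  Y[cbind(seq_len(nrow(X)), yi)] <- 1
  yv <- match(lab_va, backbone$class_order)

  ## Pooled features are poorly conditioned for plain SGD (large means,
  ## small spread), so the head is optimized on standardized features and
  ## the standardization is folded back into the stored weights afterwards:
  ## the fully-connected layer still maps *raw* features to the same scores.
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  Xvs <- sweep(sweep(Xv, 2, mu), 2, sdev, "/")

  W <- backbone$fc$W * sdev; b <- backbone$fc$b  # head in standardized space
  n <- nrow(X)
  hist_acc <- numeric(cfg$epochs)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        ix <- ord[start:min(start + cfg$batch_size - 1, n)]
        Xb <- Xs[ix, , drop = FALSE]
        P <- softmax_rows(sweep(Xb %*% W, 2, b, "+"))
        G <- P - Y[ix, , drop = FALSE]
        W <- W - cfg$learning_rate * crossprod(Xb, G) / length(ix)
        b <- b - cfg$learning_rate * colMeans(G)
      }
      pred <- max.col(sweep(Xvs %*% W, 2, b, "+"), ties.method = "first")
      hist_acc[ep] <- mean(pred == yv)
    }
  })
  backbone$fc <- list(W = W / sdev, b = as.vector(b - (mu / sdev) %*% W))
  backbone$history <- list(val_accuracy = hist_acc)
  backbone
}

#' Projection weights of the fully-connected layer
#'
#' Returns the final fully-connected layer's weights oriented `F x C`, its
#' bias, and the class order of the columns. Projecting a pooled feature
#' vector through these weights reproduces the backbone's pre-softmax class
#' scores; the rows of the retrieval lookup table are exactly such
#' projections.
#'
#' @param backbone An `oto_backbone`.
#' @return An object of class `oto_projection`: list with `W` (`F x C`
#'   matrix), `b` (length-`C` bias) and `class_order`.
#' @export
get_projection <- function(backbone) {
  stopifnot(inherits(backbone, "oto_backbone"))
  if (is.null(backbone$fc))
    stop("backbone lacks a fully-connected layer", call. = FALSE)
  structure(
    list(W = backbone$fc$W, b = backbone$fc$b,
         class_order = backbone$class_order),
    class = "oto_projection"
  )
}

#' Parameters of the frozen layers
#'
#' The frozen convolutional weights and biases, suitable for checking freeze
#' integrity across training runs (e.g. with [identical()]).
#'
#' @param backbone An `oto_backbone`.
#' @return List of the frozen layers' parameter arrays.
#' @export
frozen_parameters <- function(backbone) {
  stopifnot(inherits(backbone, "oto_backbone"))
  backbone$conv[seq_len(backbone$frozen_layer_count)]
}
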