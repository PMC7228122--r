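#' Configuration of the handcrafted baseline feature vector
#'
#' The baseline descriptor concatenates, in order: a joint HSV colour
#' histogram, a colour autocorrelogram, the first two colour moments of each
#' RGB channel, and Gabor wavelet texture statistics of the grayscale image.
#' None of these hyperparameters is dictated by the retrieval method; the
#' defaults are the common CBIR choices (compact 8x2x2 joint HSV histogram,
#' 64 quantized colours at chessboard distances 1/3/5/7, a 4-scale x
#' 6-orientation Gabor bank).
#'
#' @param hsv_bins Integer `(h, s, v)` bin counts.
#' @param correlogram_distances Positive integer pixel offsets.
#' @param correlogram_levels Quantized colour count; must be a cube of a
#'   per-channel level count (8, 27, 64, 125, ...), at least 8.
#' @param gabor_scales,gabor_orientations Filter-bank dimensions.
#' @return An object of class `handcrafted_config`.
#' @export
handcrafted_config <- function(hsv_bins = c(8, 2, 2),
                               correlogram_distances = c(1, 3, 5, 7),
                               correlogram_levels = 64,
                               gabor_scales = 4, gabor_orientations = 6) {
  stopifnot(length(hsv_bins) == 3, all(hsv_bins >= 1),
            all(correlogram_distances >= 1),
            correlogram_levels >= 8,
            gabor_scales >= 1, gabor_orientations >= 1)
  per_ch <- round(correlogram_levels^(1 / 3))
  if (per_ch^3 != correlogram_levels)
    stop("`correlogram_levels` must be a perfect cube (per-channel quantization)",
         call. = FALSE)
  structure(
    list(hsv_bins = as.integer(hsv_bins),
         correlogram_distances = as.integer(correlogram_distances),
         correlogram_levels = as.integer(correlogram_levels),
         gabor_scales = as.integer(gabor_scales),
         gabor_orientations = as.integer(gabor_orientations)),
    class = "handcrafted_config"
  )
}

#' Joint HSV colour histogram
#'
#' Converts the image to HSV and bins all pixels into a joint
#' `h_bins x s_bins x v_bins` histogram, L1-normalized to sum 1. Bin edges
#' are uniform on `[0, 1]` per channel; the top edge is inclusive.
#'
#' @param image An [oto_image()].
#' @param bins Integer `(h, s, v)` bin counts.
#' @return Numeric vector of length `prod(bins)` summing to 1, ordered with
#'   the hue index varying fastest.
#' @export
hsv_histogram <- function(image, bins = c(8, 2, 2)) {
  stopifnot(is_oto_image(image), length(bins) == 3)
  px <- image$pixels
  n <- prod(dim(px)[1:2])
  if (n == 0) stop("empty image", call. = FALSE)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsvm <- rgb2hsv(m, maxColorValue = 255)
  bh <- pmin(floor(hsvm[1, ] * bins[1]), bins[1] - 1)
  bs <- pmin(floor(hsvm[2, ] * bins[2]), bins[2] - 1)
  bv <- pmin(floor(hsvm[3, ] * bins[3]), bins[3] - 1)
  idx <- 1 + bh + bins[1] * (bs + bins[2] * bv)
  tabulate(idx, nbins = prod(bins)) / n
}

## Per-channel uniform quantization of 0..255 into `per_ch` levels; returns
## an h x w integer matrix of colour codes in 1..per_ch^3.
quantize_colors <- function(pixels, levels) {
  per_ch <- round(levels^(1 / 3))
  q <- pmin(floor(pixels / 256 * per_ch), per_ch - 1)
  1L + q[, , 1] + per_ch * (q[, , 2] + per_ch * q[, , 3])
}

#' Colour autocorrelogram
#'
#' Colours are quantized to `levels` values; for each colour `c` and each
#' distance `d`, the value is the probability that a pixel at chessboard
#' (L-infinity) distance exactly `d` from a pixel of colour `c` also has
#' colour `c`, with neighbours falling outside the image excluded from the
#' denominator. Colours absent from the image get 0. The vector is ordered
#' colour-major, distance-minor.
#'
#' @param image An [oto_image()].
#' @param distances Positive integer distances.
#' @param levels Quantized colour count (perfect cube).
#' @return Numeric vector of length `levels * length(distances)`, entries in
#'   `[0, 1]`.
#' @export
color_autocorrelogram <- function(image, distances = c(1, 3, 5, 7),
                                  levels = 64) {
  stopifnot(is_oto_image(image), all(distances >= 1))
  q <- quantize_colors(image$pixels, levels)
  h <- nrow(q); w <- ncol(q)
  same <- matrix(0, levels, length(distances))
  tot <- matrix(0, levels, length(distances))
  for (di in seq_along(distances)) {
    d <- distances[di]
    offs <- chessboard_ring(d)
    for (oi in seq_len(nrow(offs))) {
      dr <- offs[oi, 1]; dc <- offs[oi, 2]
      r1 <- max(1, 1 - dr):min(h, h - dr)
      c1 <- max(1, 1 - dc):min(w, w - dc)
      if (length(r1) == 0 || length(c1) == 0) next
      a <- q[r1, c1, drop = FALSE]
      b <- q[r1 + dr, c1 + dc, drop = FALSE]
      tot[, di] <- tot[, di] + tabulate(a, nbins = levels)
      eq <- a == b
      if (any(eq))
        same[, di] <- same[, di] + tabulate(a[eq], nbins = levels)
    }
  }
  p <- ifelse(tot > 0, same / tot, 0)
  as.vector(t(p))  # colour-major, distance-minor
}

## All (dr, dc) offsets at chessboard distance exactly d (8d of them).
chessboard_ring <- function(d) {
  offs <- expand.grid(dr = -d:d, dc = -d:d)
  as.matrix(offs[pmax(abs(offs$dr), abs(offs$dc)) == d, , drop = FALSE])
}

#' First two colour moments per RGB channel
#'
#' Mean and population standard deviation of each channel, ordered
#' `(meanR, sdR, meanG, sdG, meanB, sdB)` on the 0-255 scale.
#'
#' @param image An [oto_image()].
#' @return Numeric vector of length 6.
#' @export
color_moments <- function(image) {
  stopifnot(is_oto_image(image))
  out <- numeric(6)
  for (ch in 1:3) {
    v <- as.vector(image$pixels[, , ch])
    out[2 * ch - 1] <- mean(v)
    out[2 * ch] <- sqrt(mean((v - mean(v))^2))
  }
  out
}

#' Gabor filter bank
#'
#' Complex Gabor kernels at `scales` wavelengths (3 px growing by factor
#' 1.5) and `orientations` evenly spaced angles. The cosine (even) part has
#' its mean removed so every kernel is zero-mean; the sine (odd) part is
#' zero-mean by symmetry.
#'
#' @param scales,orientations Bank dimensions.
#' @return List of `scales * orientations` entries (scale-major), each a
#'   list with `even` and `odd` kernel matrices, `wavelength`, `theta`.
#' @export
gabor_bank <- function(scales = 4, orientations = 6) {
  bank <- list()
  gamma <- 0.8
  for (s in seq_len(scales)) {
    lambda <- 3 * 1.5^(s - 1)
    sigma <- 0.5 * lambda
    half <- ceiling(2.5 * sigma)
    xs <- -half:half
    X <- matrix(xs, length(xs), length(xs))
    Y <- t(X)
    for (o in seq_len(orientations)) {
      theta <- (o - 1) * pi / orientations
      xp <- X * cos(theta) + Y * sin(theta)
      yp <- -X * sin(theta) + Y * cos(theta)
      env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
      even <- env * cos(2 * pi * xp / lambda)
      odd <- env * sin(2 * pi * xp / lambda)
      bank[[length(bank) + 1L]] <- list(
        even = even - mean(even), odd = odd,
        wavelength = lambda, theta = theta)
    }
  }
  bank
}

#' Gabor wavelet texture features
#'
#' The grayscale (Rec. 601) image is convolved with each complex kernel of
#' the bank (replicated borders); per kernel the mean and population
#' standard deviation of the response magnitude are recorded, giving a
#' vector of length `2 * scales * orientations` (scale-major,
#' orientation-minor; mean before sd).
#'
#' @param image An [oto_image()].
#' @param scales,orientations Bank dimensions (see [gabor_bank()]).
#' @return Numeric feature vector.
#' @export
gabor_features <- function(image, scales = 4, orientations = 6) {
  stopifnot(is_oto_image(image))
  gray <- luminance(image$pixels) / 255
  bank <- gabor_bank(scales, orientations)
  ksize <- max(vapply(bank, function(k) nrow(k$even), numeric(1)))
  if (ksize > min(dim(gray)))
    stop(sprintf("largest Gabor kernel (%dpx) exceeds image size", ksize),
         call. = FALSE)
  out <- numeric(2 * length(bank))
  for (i in seq_along(bank)) {
    re <- EBImage::filter2(gray, bank[[i]]$even, boundary = "replicate")
    im <- EBImage::filter2(gray, bank[[i]]$odd, boundary = "replicate")
    mag <- sqrt(re^2 + im^2)
    out[2 * i - 1] <- mean(mag)
    out[2 * i] <- sqrt(mean((mag - mean(mag))^2))
  }
  out
}

#' Compose the handcrafted baseline descriptor
#'
#' Concatenates, in order: HSV histogram, colour autocorrelogram, colour
#' moments, Gabor features. The attribute `segments` records the index span
#' of each family. When a `standardizer` (from [f1_standardizer()]) is
#' supplied, each coordinate is z-scored with the training-set statistics;
#' without one the raw concatenation is returned.
#'
#' @param image An [oto_image()].
#' @param config A [handcrafted_config()].
#' @param standardizer Optional output of [f1_standardizer()].
#' @return Numeric vector with attribute `segments` (named list of index
#'   ranges).
#' @export
compose_f1 <- function(image, config = handcrafted_config(),
                       standardizer = NULL) {
  stopifnot(inherits(config, "handcrafted_config"))
  parts <- list(
    hsv = hsv_histogram(image, config$hsv_bins),
    autocorrelogram = color_autocorrelogram(image, config$correlogram_distances,
                                            config$correlogram_levels),
    moments = color_moments(image),
    gabor = gabor_features(image, config$gabor_scales,
                           config$gabor_orientations)
  )
  v <- unlist(parts, use.names = FALSE)
  lens <- vapply(parts, length, integer(1))
  stops <- cumsum(lens)
  segments <- Map(function(a, b) a:b, stops - lens + 1, stops)
  if (!is.null(standardizer)) {
    if (length(standardizer$center) != length(v))
      stop("standardizer length does not match descriptor", call. = FALSE)
    v <- (v - standardizer$center) / standardizer$scale
  }
  attr(v, "segments") <- segments
  v
}

#' Handcrafted descriptors for a list of images
#'
#' @param images List of [oto_image()].
#' @param config A [handcrafted_config()].
#' @param standardizer Optional [f1_standardizer()] output.
#' @return `N x L` matrix with image ids as row names and attribute
#'   `segments`.
#' @export
compose_f1_matrix <- function(images, config = handcrafted_config(),
                              standardizer = NULL) {
  vs <- lapply(images, compose_f1, config = config, standardizer = standardizer)
  m <- do.call(rbind, vs)
  rownames(m) <- image_ids(images)
  attr(m, "segments") <- attr(vs[[1]], "segments")
  m
}

#' Fit per-coordinate standardization statistics
#'
#' Mean and population standard deviation of each descriptor coordinate over
#' a training matrix. Coordinates with zero spread get scale 1 so they map
#' to 0 rather than NaN.
#'
#' @param train_matrix `N x L` raw descriptor matrix (see
#'   [compose_f1_matrix()]).
#' @return List with `center` and `scale` vectors.
#' @export
f1_standardizer <- function(train_matrix) {
  center <- colMeans(train_matrix)
  scale <- sqrt(colMeans(sweep(train_matrix, 2, center)^2))
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

## -- baseline classifiers ------------------------------------------------

#' Fit a baseline classifier on handcrafted descriptors
#'
#' @param x `N x L` (standardized) descriptor matrix.
#' @param labels Length-`N` class labels; at least two classes must occur.
#' @param method `"knn"` (class-vote fractions among the `k` nearest
#'   training points, Euclidean distance) or `"svm"` (linear-kernel
#'   one-vs-rest support vector machines; scores are decision values).
#' @param params List of hyperparameters: `k` for KNN (default 5), `cost`
#'   for SVM (default 1).
#' @param class_order Score-column order (defaults to sorted unique labels).
#' @return An object of class `oto_baseline`.
#' @export
fit_baseline <- function(x, labels, method = c("knn", "svm"),
                         params = list(), class_order = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("baseline training set must contain at least two classes", call. = FALSE)
  if (is.null(class_order)) class_order <- sort(unique(labels))
  model <- list(method = method, x = x, labels = labels,
                class_order = class_order)
  if (method == "knn") {
    model$k <- if (is.null(params$k)) 5L else as.integer(params$k)
  } else {
    cost <- if (is.null(params$cost)) 1 else params$cost
    model$svms <- lapply(class_order, function(cl) {
      y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
      e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    })
  }
  structure(model, class = "oto_baseline")
}

#' Class-score vectors from a fitted baseline
#'
#' KNN: for each query row, the fraction of its `k` nearest training points
#' (Euclidean distance, ties broken by training index) belonging to each
#' class. A training point scored against its own training set is its own
#' nearest neighbour (distance 0). SVM: the one-vs-rest decision values
#' (positive favours the class).
#'
#' @param model An [fit_baseline()] result.
#' @param newx `M x L` matrix of query descriptors.
#' @return `M x C` score matrix, columns in `model$class_order`.
#' @export
baseline_scores <- function(model, newx) {
  stopifnot(inherits(model, "oto_baseline"))
  newx <- as.matrix(newx)
  C <- length(model$class_order)
  if (model$method == "knn") {
    k <- min(model$k, nrow(model$x))
    cross <- newx %*% t(model$x)
    d2 <- outer(rowSums(newx^2), rowSums(model$x^2), "+") - 2 * cross
    scores <- matrix(0, nrow(newx), C,
                     dimnames = list(NULL, model$class_order))
    for (i in seq_len(nrow(newx))) {
      nb <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
      votes <- table(factor(model$labels[nb], levels = model$class_order))
      scores[i, ] <- as.numeric(votes) / k
    }
    scores
  } else {
    scores <- vapply(seq_len(C), function(ci) {
      pr <- predict(model$svms[[ci]], newx, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      ## e1071 orients the decision value toward the first factor level
      ## ("pos"); flip if the column header says otherwise.
      if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
    }, numeric(nrow(newx)))
    scores <- matrix(scores, nrow(newx), C,
                     dimnames = list(NULL, model$class_order))
    scores
  }
}

#' Baseline score lookup table
#'
#' Fits the named classifier on the training descriptors and scores each
#' training image with it; the resulting `N x C` class-score rows form a
#' lookup table structurally identical to the deep one, so the same
#' [retrieve()] and evaluation machinery applies to the baselines.
#'
#' @inheritParams fit_baseline
#' @param ids Length-`N` unique image ids (defaults to row names of `x`).
#' @return An `oto_lookup` with the fitted model attached as attribute
#'   `model`.
#' @export
baseline_score_table <- function(x, labels, method = c("knn", "svm"),
                                 params = list(), ids = NULL,
                                 class_order = NULL) {
  x <- as.matrix(x)
  if (is.null(ids)) ids <- rownames(x)
  if (is.null(ids) || anyDuplicated(ids))
    stop("`ids` must be unique, one per training row", call. = FALSE)
  model <- fit_baseline(x, labels, method, params, class_order)
  rows <- baseline_scores(model, x)
  tab <- structure(
    list(rows = rows, ids = as.character(ids), labels = as.character(labels),
         class_order = model$class_order),
    class = "oto_lookup"
  )
  attr(tab, "model") <- model
  tab
}
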