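#' Project a feature vector into class-score space
#'
#' The heart of the retrieval method: the transpose of the pooled feature
#' vector is multiplied by the fully-connected weight matrix, mapping the
#' length-`F` feature vector to a length-`C` vector of class scores
#' (`f' W`, plus the layer bias when `use_bias` is on, matching the
#' backbone's own pre-softmax output). Raw scores are used, not softmax
#' probabilities.
#'
#' @param feature Numeric length-`F` vector.
#' @param pw An `oto_projection` (see [get_projection()]).
#' @param use_bias Include the fully-connected bias (default `TRUE`).
#' @return Numeric length-`C` vector named by class order.
#' @export
project <- function(feature, pw, use_bias = TRUE) {
  stopifnot(inherits(pw, "oto_projection"))
  if (length(feature) != nrow(pw$W))
    stop(sprintf("feature length %d does not match projection rows %d",
                 length(feature), nrow(pw$W)), call. = FALSE)
  v <- as.vector(feature %*% pw$W)
  if (use_bias) v <- v + pw$b
  setNames(v, pw$class_order)
}

#' Build the retrieval lookup table
#'
#' Each database (training) image's pooled feature vector is projected into
#' the class-score subspace; the projections, stacked as rows of an `N x C`
#' matrix with parallel id and label vectors, constitute the lookup table.
#' Queries are answered by nearest-row search in this table.
#'
#' @param features `N x F` matrix (rows in image order) or list of length-`F`
#'   vectors.
#' @param labels Character vector of `N` class labels.
#' @param pw An `oto_projection`.
#' @param ids Character vector of `N` unique image ids; defaults to the
#'   feature matrix row names.
#' @param use_bias Passed to [project()].
#' @param normalize L2-normalize the rows (off by default; raw class scores
#'   are stored).
#' @return An object of class `oto_lookup`: list with `rows` (`N x C`),
#'   `ids`, `labels`, `class_order`.
#' @export
build_lookup <- function(features, labels, pw, ids = NULL, use_bias = TRUE,
                         normalize = FALSE) {
  stopifnot(inherits(pw, "oto_projection"))
  if (is.list(features)) features <- do.call(rbind, features)
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty feature set", call. = FALSE)
  if (is.null(ids)) ids <- rownames(features)
  if (is.null(ids) || length(ids) != nrow(features))
    stop("`ids` must give one id per feature row", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate image ids", call. = FALSE)
  if (length(labels) != nrow(features))
    stop("`labels` must give one label per feature row", call. = FALSE)
  if (ncol(features) != nrow(pw$W))
    stop("feature dimension does not match projection", call. = FALSE)
  rows <- features %*% pw$W
  if (use_bias) rows <- sweep(rows, 2, pw$b, "+")
  if (normalize) {
    nrm <- sqrt(rowSums(rows^2))
    if (any(nrm == 0)) stop("cannot normalize a zero score row", call. = FALSE)
    rows <- rows / nrm
  }
  colnames(rows) <- pw$class_order
  rownames(rows) <- NULL
  structure(
    list(rows = rows, ids = as.character(ids), labels = as.character(labels),
         class_order = pw$class_order),
    class = "oto_lookup"
  )
}

#' @export
print.oto_lookup <- function(x, ...) {
  cat(sprintf("<oto_lookup> %d rows x %d classes (%s)\n",
              nrow(x$rows), ncol(x$rows), paste(x$class_order, collapse = ", ")))
  invisible(x)
}

#' Chebyshev (L-infinity) distance
#'
#' `max_j |x_j - y_j|`.
#'
#' @param x,y Numeric vectors of equal length with finite entries.
#' @return Non-negative scalar.
#' @export
chebyshev_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  max(abs(x - y))
}

#' Cosine distance
#'
#' `1 - (x . y) / (||x|| ||y||)`, in `[0, 2]`.
#'
#' @param x,y Numeric vectors of equal length; both must have nonzero norm
#'   (the cosine of a zero vector is undefined and raises an error).
#' @return Scalar in `[0, 2]`.
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("undefined cosine: zero-norm vector", call. = FALSE)
  1 - sum(x * y) / (nx * ny)
}

## Distances from one query row to every table row, vectorized.
lookup_distances <- function(query, rows, metric) {
  switch(metric,
    chebyshev = apply(abs(sweep(rows, 2, query)), 1, max),
    cosine = {
      nq <- sqrt(sum(query^2))
      nr <- sqrt(rowSums(rows^2))
      if (nq == 0) stop("undefined cosine: zero-norm query", call. = FALSE)
      if (any(nr == 0)) stop("undefined cosine: zero-norm table row", call. = FALSE)
      1 - as.vector(rows %*% query) / (nr * nq)
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Retrieve the most similar database images
#'
#' Computes the distance from the query's class-score vector to every lookup
#' row, sorts ascending (ties broken by insertion index, so results are
#' deterministic), and returns the top `min(k, N)`.
#'
#' @param query Numeric length-`C` class-score vector (a projected feature
#'   vector, see [project()]).
#' @param table An [build_lookup()] table.
#' @param k Positive integer, number of images to retrieve.
#' @param metric `"chebyshev"` or `"cosine"`.
#' @param query_id Optional id recorded in the result.
#' @return An object of class `oto_query_result`: data frame with columns
#'   `rank`, `id`, `label`, `distance` (non-decreasing), plus attributes
#'   `metric`, `k`, `query_id`.
#' @export
retrieve <- function(query, table, k, metric = c("chebyshev", "cosine"),
                     query_id = NA_character_) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "oto_lookup"), k >= 1)
  if (length(query) != ncol(table$rows))
    stop("query length does not match table width", call. = FALSE)
  d <- lookup_distances(query, table$rows, metric)
  ord <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
  res <- data.frame(
    rank = seq_along(ord),
    id = table$ids[ord],
    label = table$labels[ord],
    distance = d[ord],
    stringsAsFactors = FALSE
  )
  structure(res, class = c("oto_query_result", "data.frame"),
            metric = metric, k = as.integer(k), query_id = query_id)
}

#' Write / read a lookup table as CSV
#'
#' Columns: `id`, `label`, then one `score_<class>` column per class.
#'
#' @param table An `oto_lookup`.
#' @param path CSV file path.
#' @return `write_lookup` invisibly returns `path`; `read_lookup` returns an
#'   `oto_lookup`.
#' @export
write_lookup <- function(table, path) {
  stopifnot(inherits(table, "oto_lookup"))
  df <- data.frame(id = table$ids, label = table$labels,
                   table$rows, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("score_", table$class_order)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  score_cols <- grep("^score_", names(df), value = TRUE)
  rows <- as.matrix(df[score_cols])
  class_order <- sub("^score_", "", score_cols)
  colnames(rows) <- class_order
  structure(
    list(rows = rows, ids = df$id, labels = df$label,
         class_order = class_order),
    class = "oto_lookup"
  )
}
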