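#' Stratified k-fold splits with nested train/validation
#'
#' The dataset is divided into `n_folds` random folds, stratified so that
#' each fold's test set has a similar number of images from each category.
#' Within each fold the remaining images are split, again per class, into
#' train (70%) and validation (30%). Across folds the test sets are disjoint
#' and together cover the whole dataset.
#'
#' @param labels Character vector of class labels; every class must have at
#'   least `n_folds` members.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; identical inputs give identical splits.
#' @param train_frac Fraction of the non-test remainder used for training
#'   (default 0.7).
#' @return List of `n_folds` fold objects, each a list with elements `fold`,
#'   `test`, `train`, `validation` (integer index vectors into `labels`).
#' @export
stratified_kfold <- function(labels, n_folds = 10, seed = 1, train_frac = 0.7) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("every class needs at least `n_folds` members; smallest has ",
         min(counts), call. = FALSE)
  withr::with_seed(as.integer(seed), {
    ## per class: shuffle, deal members round-robin into folds
    fold_of <- integer(length(labels))
    shuffled <- list()
    for (cl in names(counts)) {
      ix <- which(labels == cl)
      ix <- ix[sample.int(length(ix))]
      shuffled[[cl]] <- ix
      fold_of[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
    lapply(seq_len(n_folds), function(f) {
      test <- integer(0); train <- integer(0); val <- integer(0)
      for (cl in names(counts)) {
        ix <- shuffled[[cl]]
        te <- ix[fold_of[ix] == f]
        rem <- ix[fold_of[ix] != f]
        n_tr <- round(train_frac * length(rem))
        test <- c(test, te)
        train <- c(train, rem[seq_len(n_tr)])
        val <- c(val, rem[setdiff(seq_along(rem), seq_len(n_tr))])
      }
      list(fold = f, test = sort(test), train = sort(train),
           validation = sort(val))
    })
  })
}

#' Pooled retrieval accuracy
#'
#' The fraction of all retrieved items, pooled over every query, whose label
#' matches the query's label: `sum_q #(correct in top-k) / sum_q min(k, N)`.
#' At `k = 1` this is the plain fraction of queries whose nearest neighbour
#' has the right class.
#'
#' @param results List of [retrieve()] results, one per query.
#' @param query_labels Character vector of the query labels.
#' @return Scalar in `[0, 1]`.
#' @export
retrieval_accuracy <- function(results, query_labels) {
  if (length(results) == 0) stop("no query results", call. = FALSE)
  stopifnot(length(results) == length(query_labels))
  correct <- 0; total <- 0
  for (i in seq_along(results)) {
    if (nrow(results[[i]]) == 0) stop("empty query result", call. = FALSE)
    correct <- correct + sum(results[[i]]$label == query_labels[i])
    total <- total + nrow(results[[i]])
  }
  correct / total
}

#' Per-category precision and recall at k
#'
#' For category `c`, precision is the number of class-`c` items retrieved
#' for class-`c` queries divided by the total number of items retrieved for
#' those queries; recall divides the same numerator by the number of
#' relevant database images, counted per query as the database count of the
#' query's class and summed over the class-`c` queries. Categories with no
#' queries are reported as `NA` rather than 0.
#'
#' The count of "relevant images in the database" admits two readings:
#' `relevant = "database"` (default) charges each query the full database
#' count of its class, so recall at small `k` is bounded by
#' `k / class size`; `relevant = "capped"` caps the per-query charge at
#' `min(k, class size)`, the usual per-query recall-at-k, under which a
#' perfect retriever reaches recall 1 at every depth.
#'
#' @param results List of [retrieve()] results.
#' @param query_labels Character vector of query labels.
#' @param database_labels Character vector of all database (lookup-table)
#'   labels.
#' @param k Retrieval depth; results are truncated to their top `k` rows.
#' @param relevant Recall denominator convention, see Details.
#' @return Data frame with columns `category`, `precision`, `recall`,
#'   `f1`, `n_queries`.
#' @export
precision_recall_at_k <- function(results, query_labels, database_labels, k,
                                  relevant = c("database", "capped")) {
  relevant <- match.arg(relevant)
  stopifnot(length(results) == length(query_labels), k >= 1)
  cats <- sort(unique(c(query_labels, database_labels)))
  db_count <- table(factor(database_labels, levels = cats))
  out <- data.frame(category = cats, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, n_queries = 0L, stringsAsFactors = FALSE)
  for (ci in seq_along(cats)) {
    cl <- cats[ci]
    qs <- which(query_labels == cl)
    out$n_queries[ci] <- length(qs)
    if (length(qs) == 0) next
    tp <- 0; retrieved <- 0
    for (q in qs) {
      top <- head(results[[q]], k)
      tp <- tp + sum(top$label == cl)
      retrieved <- retrieved + nrow(top)
    }
    per_query <- if (relevant == "capped") min(k, db_count[[cl]])
                 else db_count[[cl]]
    n_relevant <- length(qs) * per_query
    out$precision[ci] <- tp / retrieved
    out$recall[ci] <- if (n_relevant > 0) tp / n_relevant else NA_real_
    out$f1[ci] <- f1_score(out$precision[ci], out$recall[ci])
  }
  out
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2pr / (p + r)`, defined as 0 when
#' both are 0. Vectorized.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return Values in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' One-vs-rest multiclass accuracy
#'
#' Resolves the binary accuracy formula `(TP + TN) / total` for `C` classes
#' by binarizing one-vs-rest. `"micro"` (default) sums TP and TN over the
#' `C` binary problems before dividing by `C * n`; `"macro"` averages the
#' per-class binary accuracies; `"fraction"` is the plain fraction of
#' correct predictions. For binary labels all three coincide with the direct
#' formula.
#'
#' @param predicted,true Equal-length label vectors.
#' @param average One of `"micro"`, `"macro"`, `"fraction"`.
#' @return Scalar in `[0, 1]`.
#' @export
multiclass_accuracy <- function(predicted, true,
                                average = c("micro", "macro", "fraction")) {
  average <- match.arg(average)
  if (length(predicted) != length(true)) stop("length mismatch", call. = FALSE)
  predicted <- as.character(predicted); true <- as.character(true)
  if (average == "fraction") return(mean(predicted == true))
  classes <- sort(unique(c(predicted, true)))
  n <- length(true)
  acc <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & true == cl)
    tn <- sum(predicted != cl & true != cl)
    (tp + tn) / n
  }, numeric(1))
  if (average == "macro") mean(acc) else sum(acc * n) / (length(classes) * n)
}

#' Experiment configuration
#'
#' @param method `"deep"` (lookup table from the tiny CNN), `"knn"` or
#'   `"svm"` (handcrafted-feature baselines), or `"random"` (null baseline:
#'   the score table is seeded noise, so retrieval is label-independent).
#' @param n_folds Cross-validation folds (default 5 for desk-scale runs; the
#'   full protocol uses 10).
#' @param k_values Retrieval depths evaluated.
#' @param metrics Distance metrics evaluated.
#' @param use_bias Include the fully-connected bias in projections.
#' @param normalize L2-normalize lookup rows (off by default).
#' @param balance Balance training classes by augmented resampling.
#' @param recall_relevant Recall denominator convention for the per-category
#'   table (see [precision_recall_at_k()]).
#' @param backbone_args Arguments for [tiny_backbone()] (seed is managed by
#'   the harness).
#' @param train_cfg A [train_config()] (its seed is re-derived per fold).
#' @param augmentation An [augmentation_spec()] for class balancing.
#' @param handcrafted A [handcrafted_config()] for the baselines.
#' @param baseline_params Passed to [fit_baseline()].
#' @param seed Master seed; all splits, balancing, initialization and
#'   training randomness derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(method = c("deep", "knn", "svm", "random"),
                              n_folds = 5, k_values = c(1, 3, 5, 7, 9),
                              metrics = c("chebyshev", "cosine"),
                              use_bias = TRUE, normalize = FALSE,
                              balance = TRUE,
                              recall_relevant = c("database", "capped"),
                              backbone_args = list(),
                              train_cfg = train_config(),
                              augmentation = augmentation_spec(),
                              handcrafted = handcrafted_config(),
                              baseline_params = list(),
                              seed = 1) {
  method <- match.arg(method)
  recall_relevant <- match.arg(recall_relevant)
  stopifnot(length(k_values) >= 1, all(k_values >= 1),
            all(metrics %in% c("chebyshev", "cosine")))
  structure(
    list(method = method, n_folds = as.integer(n_folds),
         k_values = as.integer(k_values), metrics = metrics,
         use_bias = use_bias, normalize = normalize, balance = balance,
         recall_relevant = recall_relevant,
         backbone_args = backbone_args, train_cfg = train_cfg,
         augmentation = augmentation, handcrafted = handcrafted,
         baseline_params = baseline_params, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

## Score every query image and the lookup table for one fold of one method.
## Returns list(table, query_scores (M x C matrix), val_accuracy or NA).
fold_scores <- function(images, fold, config, shared = NULL) {
  train_imgs <- images[fold$train]
  val_imgs <- images[fold$validation]
  test_imgs <- images[fold$test]
  train_labels <- image_labels(train_imgs)
  fold_seed <- config$seed + 1000L * fold$fold

  if (config$method == "deep") {
    backbone <- shared$backbone
    fit_imgs <- train_imgs
    if (config$balance) {
      aug <- config$augmentation
      aug$seed <- fold_seed
      fit_imgs <- balance_classes(train_imgs, aug)
    }
    cfg <- config$train_cfg
    cfg$seed <- fold_seed + 1L
    backbone <- fine_tune(backbone, fit_imgs, val_imgs, cfg)
    pw <- get_projection(backbone)
    feats <- extract_feature_matrix(backbone, train_imgs)
    table <- build_lookup(feats, train_labels, pw,
                          use_bias = config$use_bias,
                          normalize = config$normalize)
    qf <- extract_feature_matrix(backbone, test_imgs)
    qscores <- qf %*% pw$W
    if (config$use_bias) qscores <- sweep(qscores, 2, pw$b, "+")
    if (config$normalize) qscores <- qscores / sqrt(rowSums(qscores^2))
    val_acc <- if (length(backbone$history$val_accuracy))
      backbone$history$val_accuracy[cfg$epochs] else NA_real_
    list(table = table, query_scores = qscores, val_accuracy = val_acc)
  } else if (config$method == "random") {
    n <- length(train_imgs); C <- length(unique(image_labels(images)))
    rows <- withr::with_seed(fold_seed, matrix(rnorm(n * C), n, C))
    qscores <- withr::with_seed(fold_seed + 1L,
                                matrix(rnorm(length(test_imgs) * C),
                                       length(test_imgs), C))
    table <- structure(
      list(rows = rows, ids = image_ids(train_imgs), labels = train_labels,
           class_order = sort(unique(image_labels(images)))),
      class = "oto_lookup")
    list(table = table, query_scores = qscores, val_accuracy = NA_real_)
  } else {
    raw <- shared$f1_matrix
    std <- f1_standardizer(raw[fold$train, , drop = FALSE])
    xtr <- sweep(sweep(raw[fold$train, , drop = FALSE], 2, std$center), 2,
                 std$scale, "/")
    xte <- sweep(sweep(raw[fold$test, , drop = FALSE], 2, std$center), 2,
                 std$scale, "/")
    table <- baseline_score_table(xtr, train_labels, method = config$method,
                                  params = config$baseline_params)
    qscores <- baseline_scores(attr(table, "model"), xte)
    list(table = table, query_scores = qscores, val_accuracy = NA_real_)
  }
}

#' Run a full retrieval experiment
#'
#' For each fold: balance the training classes, fit the configured method
#' (fine-tuned CNN head, handcrafted-feature KNN/SVM, or the random null),
#' build the lookup table from training images only, and query every test
#' image at each retrieval depth under each metric. Per-fold accuracies are
#' aggregated as mean and standard deviation across folds; per-category
#' precision, recall and F1 are recorded per fold and depth.
#'
#' @param images List of [oto_image()]; every class needs at least
#'   `n_folds` members.
#' @param config An [experiment_config()].
#' @return An object of class `oto_eval_report`: list with `per_fold`
#'   (fold x metric x k accuracy rows), `per_category` (fold x metric x k x
#'   category precision/recall/F1), `summary` (metric x k mean and sd
#'   accuracy), `val_accuracy` (per fold, deep method only), `config`,
#'   `seed`.
#' @export
run_experiment <- function(images, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  labels <- image_labels(images)
  folds <- stratified_kfold(labels, config$n_folds, seed = config$seed)

  shared <- list()
  if (config$method == "deep") {
    ba <- config$backbone_args
    ba$seed <- config$seed
    shared$backbone <- do.call(tiny_backbone, ba)
  } else if (config$method %in% c("knn", "svm")) {
    shared$f1_matrix <- compose_f1_matrix(images, config$handcrafted)
  }

  per_fold <- list(); per_cat <- list(); val_acc <- numeric(0)
  kmax <- max(config$k_values)
  for (fold in folds) {
    fs <- fold_scores(images, fold, config, shared)
    test_labels <- labels[fold$test]
    val_acc <- c(val_acc, fs$val_accuracy)
    for (metric in config$metrics) {
      results <- lapply(seq_len(nrow(fs$query_scores)), function(i)
        retrieve(fs$query_scores[i, ], fs$table, kmax, metric,
                 query_id = images[[fold$test[i]]]$id))
      for (k in config$k_values) {
        topk <- lapply(results, head, k)
        acc <- retrieval_accuracy(topk, test_labels)
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          fold = fold$fold, metric = metric, k = k, accuracy = acc,
          stringsAsFactors = FALSE)
        pr <- precision_recall_at_k(results, test_labels,
                                    fs$table$labels, k,
                                    relevant = config$recall_relevant)
        pr$fold <- fold$fold; pr$metric <- metric; pr$k <- k
        per_cat[[length(per_cat) + 1L]] <- pr
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  per_cat <- do.call(rbind, per_cat)
  summary_df <- aggregate(accuracy ~ metric + k, per_fold,
                          function(a) c(mean = mean(a), sd = sd(a)))
  summary_df <- data.frame(metric = summary_df$metric, k = summary_df$k,
                           mean_accuracy = summary_df$accuracy[, "mean"],
                           sd_accuracy = summary_df$accuracy[, "sd"],
                           stringsAsFactors = FALSE)
  summary_df <- summary_df[order(summary_df$metric, summary_df$k), ]
  rownames(summary_df) <- NULL
  structure(
    list(per_fold = per_fold, per_category = per_cat, summary = summary_df,
         val_accuracy = val_acc, method = config$method,
         config = config, seed = config$seed),
    class = "oto_eval_report"
  )
}

#' @export
print.oto_eval_report <- function(x, ...) {
  cat(sprintf("<oto_eval_report> method=%s, %d folds, seed=%d\n",
              x$method, max(x$per_fold$fold), x$seed))
  cat("Mean retrieval accuracy (sd) across folds:\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s k=%d  %.4f (%.4f)\n", s$metric[i], s$k[i],
                s$mean_accuracy[i], s$sd_accuracy[i]))
  if (length(x$val_accuracy) && !all(is.na(x$val_accuracy)))
    cat(sprintf("Mean final validation classification accuracy: %.4f\n",
                mean(x$val_accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the per-fold accuracies as long-format CSV and the summary
#' (plus per-category aggregates) as JSON.
#'
#' @param report An `oto_eval_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "oto_eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "report_per_fold.csv")
  write.csv(report$per_fold, csv, row.names = FALSE)
  js <- file.path(dir, "report_summary.json")
  jsonlite::write_json(
    list(method = report$method, seed = report$seed,
         summary = report$summary,
         per_category = report$per_category,
         val_accuracy = report$val_accuracy),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv, js))
}
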