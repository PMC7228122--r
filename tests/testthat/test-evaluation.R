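test_that("stratified folds partition the data with per-class test counts", {
  labels <- rep(oto_classes(), each = 10)  # 30 items, 3 balanced classes
  folds <- stratified_kfold(labels, n_folds = 10, seed = 4)
  expect_length(folds, 10)
  all_test <- integer(0)
  for (f in folds) {
    # one test item per class per fold
    expect_equal(as.vector(table(labels[f$test])), c(1, 1, 1))
    # pairwise disjoint within the fold, union covers everything
    expect_length(intersect(f$test, f$train), 0)
    expect_length(intersect(f$test, f$validation), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$test, f$train, f$validation), seq_along(labels))
    # remainder split ~70/30 per class (27 items -> 19/8 with round())
    expect_equal(length(f$train), 18)  # round(0.7 * 9) = 6 per class
    all_test <- c(all_test, f$test)
  }
  expect_setequal(all_test, seq_along(labels))
  expect_equal(anyDuplicated(all_test), 0)
})

test_that("fold splitting is seed-deterministic and validates class sizes", {
  labels <- sample(rep(oto_classes(), times = c(25, 31, 14)))
  a <- stratified_kfold(labels, n_folds = 5, seed = 9)
  b <- stratified_kfold(labels, n_folds = 5, seed = 9)
  expect_identical(a, b)
  c <- stratified_kfold(labels, n_folds = 5, seed = 10)
  expect_false(identical(a, c))
  expect_error(stratified_kfold(rep(oto_classes(), times = c(20, 20, 3)), 5),
               "at least")
})

fake_result <- function(labels, distances = seq_along(labels)) {
  structure(
    data.frame(rank = seq_along(labels), id = paste0("r", seq_along(labels)),
               label = labels, distance = distances, stringsAsFactors = FALSE),
    class = c("oto_query_result", "data.frame"))
}

test_that("pooled retrieval accuracy counts correct retrievals over all retrieved", {
  res <- list(fake_result(c("normal", "normal", "tube")),
              fake_result(c("tube", "effusion", "effusion")))
  expect_equal(retrieval_accuracy(res, c("normal", "tube")), 0.5)  # 3 of 6
  all_right <- list(fake_result(rep("tube", 3)))
  expect_equal(retrieval_accuracy(all_right, "tube"), 1.0)
  expect_error(retrieval_accuracy(list(), character(0)), "no query results")
})

test_that("retrieval accuracy under random labels converges to chance", {
  withr::with_seed(77, {
    n <- 3000
    qlabels <- sample(oto_classes(), n, replace = TRUE)
    res <- lapply(seq_len(n), function(i)
      fake_result(sample(oto_classes(), 3, replace = TRUE)))
    acc <- retrieval_accuracy(res, qlabels)
    # binomial-ish standard error over 9000 pooled draws ~ 0.005
    expect_lt(abs(acc - 1 / 3), 0.02)
  })
})

test_that("per-category precision/recall match a hand-worked example", {
  # 3 queries, 9-image database (3 per class), k = 3
  db_labels <- rep(oto_classes(), each = 3)
  res <- list(
    fake_result(c("effusion", "effusion", "normal")),  # query effusion
    fake_result(c("normal", "tube", "tube")),          # query normal
    fake_result(c("effusion", "effusion", "effusion")) # query effusion
  )
  pr <- precision_recall_at_k(res, c("effusion", "normal", "effusion"),
                              db_labels, k = 3)
  eff <- pr[pr$category == "effusion", ]
  # effusion queries retrieved 6 items, 5 correct; relevant = 2 queries * 3
  expect_equal(eff$precision, 5 / 6)
  expect_equal(eff$recall, 5 / 6)
  nor <- pr[pr$category == "normal", ]
  expect_equal(nor$precision, 1 / 3)
  expect_equal(nor$recall, 1 / 3)
  # no tube queries: reported missing, not zero
  expect_true(is.na(pr[pr$category == "tube", "precision"]))
  expect_equal(eff$f1, f1_score(5 / 6, 5 / 6))
  # truncation: k = 1 uses only the top item
  pr1 <- precision_recall_at_k(res, c("effusion", "normal", "effusion"),
                               db_labels, k = 1)
  expect_equal(pr1[pr1$category == "effusion", "precision"], 1)
})

test_that("capped recall charges each query at most min(k, class size)", {
  db_labels <- rep(oto_classes(), each = 3)
  res <- list(fake_result(c("effusion", "effusion", "normal")),
              fake_result(c("effusion", "effusion", "effusion")))
  ql <- c("effusion", "effusion")
  un <- precision_recall_at_k(res, ql, db_labels, k = 1)
  ca <- precision_recall_at_k(res, ql, db_labels, k = 1, relevant = "capped")
  eff_u <- un[un$category == "effusion", ]
  eff_c <- ca[ca$category == "effusion", ]
  # top-1 both correct: capped recall 2/2; database recall 2/(2*3)
  expect_equal(eff_c$recall, 1)
  expect_equal(eff_u$recall, 1 / 3)
  expect_equal(eff_c$precision, eff_u$precision)  # precision unaffected
  # at k = 5 > class size 3 the cap is the class size
  ca5 <- precision_recall_at_k(res, ql, db_labels, k = 3, relevant = "capped")
  expect_equal(ca5[ca5$category == "effusion", "recall"], 5 / 6)
})

test_that("zero-correct categories yield precision and recall 0", {
  res <- list(fake_result(rep("normal", 3)))
  pr <- precision_recall_at_k(res, "tube", rep(oto_classes(), each = 3), 3)
  tube <- pr[pr$category == "tube", ]
  expect_equal(tube$precision, 0)
  expect_equal(tube$recall, 0)
  expect_equal(tube$f1, 0)
})

test_that("F1 closed forms, bounds, and formula oracle", {
  expect_equal(f1_score(0.8, 0.8), 0.8)
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_equal(f1_score(0, 0), 0)
  expect_error(f1_score(1.2, 0.5), "\\[0, 1\\]")
  withr::with_seed(8, {
    p <- runif(200); r <- runif(200)
    expect_equal(f1_score(p, r), 2 * p * r / (p + r), tolerance = 1e-12)
    f <- f1_score(p, r)
    expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
  })
})

test_that("one-vs-rest accuracy reduces to (TP+TN)/total and matches a counting oracle", {
  # binary confusion TP=4, TN=3, FP=2, FN=1 -> 7/10
  true <- c(rep("pos", 5), rep("neg", 5))
  pred <- c(rep("pos", 4), "neg", rep("neg", 3), rep("pos", 2))
  expect_equal(multiclass_accuracy(pred, true, "micro"), 0.7)
  expect_equal(multiclass_accuracy(pred, true, "macro"), 0.7)
  expect_equal(multiclass_accuracy(true, true), 1.0)
  withr::with_seed(15, {
    for (trial in 1:20) {
      t3 <- sample(oto_classes(), 40, replace = TRUE)
      p3 <- sample(oto_classes(), 40, replace = TRUE)
      # brute-force per-class TP/TN counting
      tot <- 0
      for (cl in oto_classes()) {
        tp <- sum(p3 == cl & t3 == cl); tn <- sum(p3 != cl & t3 != cl)
        tot <- tot + tp + tn
      }
      expect_equal(multiclass_accuracy(p3, t3, "micro"), tot / (3 * 40))
      expect_equal(multiclass_accuracy(p3, t3, "fraction"), mean(p3 == t3))
    }
  })
})

test_that("run_experiment produces a complete, internally consistent report", {
  imgs <- generate_dataset(synth_spec(n_per_class = 12, height = 48, width = 48,
                                      separability = 1, seed = 19))
  cfg <- experiment_config(method = "deep", n_folds = 3, k_values = c(1, 3),
                           train_cfg = train_config(epochs = 25, seed = 19),
                           seed = 19)
  rep <- run_experiment(imgs, cfg)
  # n_folds x metrics x k accuracy cells
  expect_equal(nrow(rep$per_fold), 3 * 2 * 2)
  expect_true(all(rep$per_fold$accuracy >= 0 & rep$per_fold$accuracy <= 1))
  # aggregation equals an independent mean/sd pass over the per-fold cells
  for (i in seq_len(nrow(rep$summary))) {
    cells <- rep$per_fold$accuracy[rep$per_fold$metric == rep$summary$metric[i] &
                                     rep$per_fold$k == rep$summary$k[i]]
    expect_equal(rep$summary$mean_accuracy[i], mean(cells))
    expect_equal(rep$summary$sd_accuracy[i], sd(cells))
  }
  # per-category table covers all classes at each fold/metric/k
  expect_equal(nrow(rep$per_category), 3 * 2 * 2 * 3)
  expect_true(all(rep$per_category$precision >= 0 &
                    rep$per_category$precision <= 1, na.rm = TRUE))
  # deterministic given the seed
  rep2 <- run_experiment(imgs, cfg)
  expect_identical(rep$per_fold, rep2$per_fold)
})

test_that("accuracy at k = 1 equals the fraction-correct of top-1 labels", {
  withr::with_seed(25, {
    qlabels <- sample(oto_classes(), 50, replace = TRUE)
    res <- lapply(seq_len(50), function(i) fake_result(sample(oto_classes(), 1)))
    top1 <- vapply(res, function(r) r$label[1], character(1))
    expect_equal(retrieval_accuracy(res, qlabels),
                 multiclass_accuracy(top1, qlabels, "fraction"))
  })
})

test_that("reports round-trip to CSV/JSON on disk", {
  imgs <- generate_dataset(synth_spec(n_per_class = 10, height = 32, width = 32,
                                      separability = 1, seed = 23))
  cfg <- experiment_config(method = "random", n_folds = 3, k_values = 1,
                           metrics = "chebyshev", seed = 23)
  rep <- run_experiment(imgs, cfg)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("report_per_fold.csv",
                                               "report_summary.json")))))
  back <- read.csv(file.path(dir, "report_per_fold.csv"))
  expect_equal(back$accuracy, rep$per_fold$accuracy)
  js <- jsonlite::read_json(file.path(dir, "report_summary.json"))
  expect_equal(js$method, "random")
})
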