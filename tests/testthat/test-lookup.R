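make_projection <- function(W, b = rep(0, ncol(W)),
                            classes = paste0("c", seq_len(ncol(W)))) {
  structure(list(W = W, b = b, class_order = classes),
            class = "oto_projection")
}

test_that("project computes f'W (+ b) and validates dimensions", {
  pw <- make_projection(diag(3), classes = oto_classes())
  f <- c(0.3, -1, 2)
  expect_equal(unname(project(f, pw, use_bias = FALSE)), f)
  expect_equal(unname(project(rep(0, 3), pw, use_bias = FALSE)), rep(0, 3))
  pwb <- make_projection(diag(3), b = c(1, 2, 3), classes = oto_classes())
  expect_equal(unname(project(f, pwb, use_bias = TRUE)), f + c(1, 2, 3))
  expect_error(project(rep(0, 4), pw), "does not match")
})

test_that("project agrees with an elementwise sum-of-products oracle", {
  withr::with_seed(42, {
    F <- 1536; C <- 3
    f <- rnorm(F)
    W <- matrix(rnorm(F * C), F, C)
    b <- rnorm(C)
    pw <- make_projection(W, b)
    oracle <- vapply(seq_len(C), function(j) {
      s <- 0
      for (i in seq_len(F)) s <- s + f[i] * W[i, j]
      s + b[j]
    }, numeric(1))
    expect_equal(unname(project(f, pw)), oracle, tolerance = 1e-10)
  })
})

test_that("build_lookup stacks row-wise projections, aligned and permutation-equivariant", {
  withr::with_seed(7, {
    n <- 12
    feats <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(paste0("im", 1:n), NULL))
    labels <- sample(oto_classes(), n, replace = TRUE)
    pw <- make_projection(matrix(rnorm(15), 5, 3), b = rnorm(3))
    tab <- build_lookup(feats, labels, pw)
    expect_equal(dim(tab$rows), c(n, 3))
    for (i in seq_len(n))
      expect_equal(unname(tab$rows[i, ]), unname(project(feats[i, ], pw)))
    # permuting the inputs permutes the rows identically
    p <- sample.int(n)
    tab2 <- build_lookup(feats[p, ], labels[p], pw)
    expect_equal(tab2$rows, tab$rows[p, ])
    expect_identical(tab2$ids, tab$ids[p])
    # single feature -> 1 x C table
    expect_equal(dim(build_lookup(feats[1, , drop = FALSE], labels[1], pw)$rows),
                 c(1, 3))
    expect_error(build_lookup(feats[c(1, 1), ], labels[1:2], pw,
                              ids = c("a", "a")), "duplicate")
  })
})

test_that("chebyshev distance matches its closed form and a coordinate-loop oracle", {
  expect_equal(chebyshev_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(chebyshev_distance(c(0, 0, 0), c(1, -4, 2)), 4)
  expect_error(chebyshev_distance(1:2, 1:3), "length mismatch")
  withr::with_seed(11, {
    for (i in 1:1000) {
      x <- rnorm(3); y <- rnorm(3)
      m <- 0
      for (j in 1:3) m <- max(m, abs(x[j] - y[j]))
      expect_identical(chebyshev_distance(x, y), m)
    }
  })
})

test_that("chebyshev satisfies the metric axioms on random triples", {
  withr::with_seed(13, {
    for (i in 1:300) {
      x <- rnorm(3); y <- rnorm(3); z <- rnorm(3)
      dxy <- chebyshev_distance(x, y)
      expect_gte(dxy, 0)
      expect_equal(dxy, chebyshev_distance(y, x))
      expect_lte(dxy, chebyshev_distance(x, z) + chebyshev_distance(z, y) + 1e-12)
    }
    expect_equal(chebyshev_distance(c(1, 1), c(1, 1)), 0)
  })
})

test_that("cosine distance: parallel 0, orthogonal 1, antiparallel 2, scale-invariant", {
  x <- c(0.4, -1.1, 2)
  expect_equal(cosine_distance(x, 2 * x), 0)
  expect_equal(cosine_distance(c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(cosine_distance(x, -x), 2)
  expect_error(cosine_distance(c(0, 0, 0), x), "zero-norm")
  withr::with_seed(17, {
    for (i in 1:300) {
      a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
      u <- rnorm(3); v <- rnorm(3)
      d <- cosine_distance(u, v)
      expect_gte(d, 0); expect_lte(d, 2)
      expect_equal(cosine_distance(a * u, b * v), d, tolerance = 1e-12)
    }
  })
})

test_that("retrieve equals an exhaustive compute-and-sort oracle for both metrics", {
  withr::with_seed(23, {
    rows <- matrix(rnorm(150), 50, 3)
    tab <- structure(
      list(rows = rows, ids = sprintf("db%02d", 1:50),
           labels = sample(oto_classes(), 50, replace = TRUE),
           class_order = oto_classes()),
      class = "oto_lookup")
    for (metric in c("chebyshev", "cosine")) {
      fn <- if (metric == "chebyshev") chebyshev_distance else cosine_distance
      for (rep in 1:10) {
        q <- rnorm(3)
        d <- vapply(1:50, function(i) fn(q, rows[i, ]), numeric(1))
        ord <- order(d, 1:50)
        for (k in c(1, 3, 5, 50, 75)) {
          res <- retrieve(q, tab, k, metric)
          expect_equal(nrow(res), min(k, 50))
          expect_identical(res$id, tab$ids[ord[seq_len(min(k, 50))]])
          expect_equal(res$distance, d[ord[seq_len(min(k, 50))]])
          expect_true(all(diff(res$distance) >= 0))
        }
      }
    }
  })
})

test_that("retrieve breaks ties by insertion index and finds exact matches first", {
  rows <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0.5, 0.5, 0))
  tab <- structure(
    list(rows = rows, ids = c("a", "b", "c", "d"),
         labels = c("effusion", "normal", "effusion", "tube"),
         class_order = oto_classes()),
    class = "oto_lookup")
  res <- retrieve(c(1, 0, 0), tab, 4, "chebyshev")
  expect_identical(res$id[1:2], c("a", "c"))  # equal distance 0: input order
  expect_equal(res$distance[1:2], c(0, 0))
  res2 <- retrieve(c(1, 0, 0), tab, 1, "cosine")
  expect_identical(res2$id, "a")
  expect_equal(res2$distance, 0)
  expect_error(retrieve(c(0, 0, 0), tab, 1, "cosine"), "zero-norm")
})

test_that("lookup tables round-trip through CSV", {
  withr::with_seed(3, {
    pw <- make_projection(matrix(rnorm(9), 3, 3), classes = oto_classes())
    feats <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("i", 1:5), NULL))
    tab <- build_lookup(feats, rep(oto_classes(), length.out = 5), pw)
    path <- withr::local_tempfile(fileext = ".csv")
    write_lookup(tab, path)
    back <- read_lookup(path)
    expect_identical(back$ids, tab$ids)
    expect_identical(back$labels, tab$labels)
    expect_identical(back$class_order, tab$class_order)
    expect_equal(back$rows, tab$rows, tolerance = 1e-12)
  })
})

test_that("top-1 retrieval class agrees with the backbone's own classification", {
  imgs <- sep1_images()
  labels <- image_labels(imgs)
  bb <- trained_backbone()
  pw <- get_projection(bb)
  db <- unlist(lapply(oto_classes(), function(cl) which(labels == cl)[1:20]))
  qs <- setdiff(seq_along(imgs), db)
  tab <- build_lookup(extract_feature_matrix(bb, imgs[db]), labels[db], pw)
  for (metric in c("chebyshev", "cosine")) {
    agree <- vapply(qs, function(i) {
      scores <- backbone_scores(bb, imgs[[i]])
      if (names(scores)[which.max(scores)] != imgs[[i]]$label) return(NA)  # only well-classified queries
      top <- retrieve(unname(scores), tab, 1, metric)
      top$label == names(scores)[which.max(scores)]
    }, logical(1))
    expect_gte(mean(agree, na.rm = TRUE), 0.9)
  }
})
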