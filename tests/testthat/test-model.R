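test_that("LOSO folds partition the matrix by subject", {
  m <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:10), each = 3),
    label = rep(c("expert", "novice"), each = 15)
  )
  folds <- loso_folds(m)
  expect_equal(nrow(folds), 10)
  expect_setequal(unlist(folds$test), seq_len(nrow(m)))
  expect_equal(anyDuplicated(unlist(folds$test)), 0)
  for (i in seq_len(nrow(folds))) {
    test_subj <- unique(m$subject_id[folds$test[[i]]])
    train_subj <- unique(m$subject_id[folds$train[[i]]])
    expect_equal(test_subj, folds$held_out_subject[i])
    expect_length(intersect(test_subj, train_subj), 0)
  }
  expect_error(loso_folds(m[m$subject_id == "S01", ]), class = "physioload_invalid_parameter")
})

test_that("LOSO partition holds for randomly shaped cohorts", {
  withr::with_seed(13, {
    for (i in 1:10) {
      ns <- sample(2:8, 1)
      m <- tibble::tibble(
        subject_id = rep(sprintf("P%d", 1:ns), times = sample(1:6, ns, replace = TRUE))
      )
      folds <- loso_folds(m)
      expect_equal(nrow(folds), ns)
      expect_setequal(unlist(folds$test), seq_len(nrow(m)))
    }
  })
})

test_that("metrics match the closed-form equations and the hand-worked case", {
  m <- compute_metrics(3, 2, 1, 2)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.45 / 1.35, tolerance = 1e-12)
  perfect <- compute_metrics(5, 7, 0, 0)
  expect_equal(unlist(perfect[1, 1:4]), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  zero <- compute_metrics(0, 3, 2, 1)
  expect_equal(zero$precision, 0)
  expect_equal(zero$f1, 0)
  expect_true(zero$zero_division)
  expect_error(compute_metrics(0, 0, 0, 0), class = "physioload_invalid_parameter")
  expect_error(compute_metrics(-1, 1, 1, 1), class = "physioload_invalid_parameter")
})

test_that("metrics equal brute-force confusion tallies on random cases", {
  withr::with_seed(2, {
    for (i in 1:1000) {
      n <- sample(4:40, 1)
      truth <- sample(c("expert", "novice"), n, replace = TRUE)
      pred <- sample(c("expert", "novice"), n, replace = TRUE)
      tp <- sum(pred == "expert" & truth == "expert")
      tn <- sum(pred == "novice" & truth == "novice")
      fp <- sum(pred == "expert" & truth == "novice")
      fn <- sum(pred == "novice" & truth == "expert")
      m <- compute_metrics(tp, tn, fp, fn)
      expect_identical(m$accuracy, mean(pred == truth))
      if (tp + fp > 0) expect_identical(m$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_identical(m$recall, tp / (tp + fn))
    }
  })
})

test_that("every classifier kind separates well-separated blobs", {
  m <- blob_matrix()
  train <- m[m$subject_id %in% c("n1", "e1"), ]
  test <- m[m$subject_id %in% c("n2", "e2"), ]
  for (kind in c("knn", "svm", "dt", "rf")) {
    pred <- fit_predict(classifier_spec(kind), train, test, seed = 1)
    expect_gte(mean(pred == test$label), 0.99)
  }
})

test_that("knn follows the majority of the 5 nearest neighbours", {
  train <- tibble::tibble(
    subject_id = "a",
    label = c(rep("expert", 5), rep("novice", 5)),
    f1 = c(rep(0, 5), rep(10, 5))
  )
  test <- tibble::tibble(subject_id = "b", label = "novice", f1 = 0.1)
  pred <- fit_predict(classifier_spec("knn"), train, test)
  expect_equal(as.character(pred), "expert")
})

test_that("single-class training folds raise a degenerate-fold condition", {
  train <- tibble::tibble(subject_id = "a", label = rep("expert", 10), f1 = rnorm(10))
  test <- tibble::tibble(subject_id = "b", label = "expert", f1 = 0)
  expect_error(
    fit_predict(classifier_spec("knn"), train, test),
    class = "physioload_degenerate_fold"
  )
})

test_that("label permutation drives LOSO accuracy to chance", {
  base <- withr::with_seed(77, {
    dplyr::bind_rows(lapply(1:12, function(i) {
      tibble::tibble(
        subject_id = sprintf("S%d", i),
        f1 = rnorm(20), f2 = rnorm(20), f3 = rnorm(20)
      )
    }))
  })
  accs <- vapply(1:20, function(p) {
    withr::with_seed(p, {
      labmap <- setNames(
        sample(rep(c("expert", "novice"), each = 6)),
        sprintf("S%d", 1:12)
      )
      m <- base
      m$label <- labmap[m$subject_id]
      glance(suppressWarnings(run_experiment(m, classifier_spec("knn"), seed = p)))$accuracy
    })
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("experiments are reproducible and report both aggregations", {
  m <- blob_matrix()
  r1 <- run_experiment(m, classifier_spec("rf"), seed = 7)
  r2 <- run_experiment(m, classifier_spec("rf"), seed = 7)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_setequal(r1$aggregate$aggregation, c("mean-over-folds", "pooled-windows"))
  expect_equal(nrow(r1$per_fold), 4)
  # confusion counts cover every test row
  expect_equal(sum(r1$per_fold$tp + r1$per_fold$tn + r1$per_fold$fp + r1$per_fold$fn), nrow(m))
  g <- glance(r1)
  expect_equal(g$aggregation, "mean-over-folds")
  expect_gte(g$accuracy, 0.99)
  expect_s3_class(tidy(r1), "tbl_df")
})

test_that("t-SNE embeds rows in 2-D and separates distant blobs", {
  m <- blob_matrix(n_per_subject = 75, gap = 8)
  emb <- tsne_embed(m, perplexity = 30, max_iter = 500, seed = 2)
  expect_equal(dim(as.matrix(emb[, c("dim1", "dim2")])), c(nrow(m), 2))
  expect_gt(attr(emb, "silhouette"), 0.5)
  emb2 <- tsne_embed(m, perplexity = 30, max_iter = 500, seed = 2)
  expect_identical(emb$dim1, emb2$dim1)
  # too few rows: perplexity is reduced with a warning, not an error
  expect_warning(
    tsne_embed(m[1:20, ], perplexity = 30, max_iter = 100, seed = 1),
    "perplexity"
  )
})
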