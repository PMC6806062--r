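#' Classifier specification
#'
#' Captures the classifier family and its hyperparameters:
#' * `svm`: support vector machine with polynomial kernel of degree 2,
#'   regularization `cost` (default 1);
#' * `dt`: decision tree, Gini impurity, grown without depth bound;
#' * `rf`: random forest of `ntree` trees (default 100);
#' * `knn`: k-nearest neighbours with `k = 5`, uniform weights, Euclidean
#'   distance.
#'
#' @param kind One of `"knn"`, `"svm"`, `"dt"`, `"rf"`.
#' @param cost SVM regularization parameter.
#' @param degree SVM polynomial degree.
#' @param coef0 Additive constant of the polynomial kernel
#'   `(gamma u'v + coef0)^degree`; the default 1 gives the standard
#'   inhomogeneous kernel (a homogeneous one is blind to sign flips of
#'   standardized features).
#' @param ntree Number of random-forest trees.
#' @param k Number of KNN neighbours.
#' @return A list of class `classifier_spec`.
#' @examples
#' classifier_spec("knn")
#' @export
classifier_spec <- function(kind = c("knn", "svm", "dt", "rf"),
                            cost = 1, degree = 2, coef0 = 1, ntree = 100,
                            k = 5) {
  kind <- match.arg(kind)
  structure(
    list(
      kind = kind, cost = cost, degree = degree, coef0 = coef0,
      ntree = ntree, k = k
    ),
    class = "classifier_spec"
  )
}

#' Leave-one-subject-out folds
#'
#' Partitions a feature matrix into one fold per subject: the test set is
#' all windows of exactly one subject, the training set all windows of the
#' others. Folds cover every subject exactly once and never share a subject
#' between train and test.
#'
#' @param matrix A [assemble_matrix()] tibble (needs a `subject_id` column).
#' @return A tibble with columns `held_out_subject`, `train` and `test`
#'   (list-columns of row indices into `matrix`).
#' @examples
#' m <- tibble::tibble(subject_id = rep(c("a", "b"), each = 3), label = "expert")
#' loso_folds(m)
#' @export
loso_folds <- function(matrix) {
  subjects <- unique(matrix$subject_id)
  if (length(subjects) < 2L) {
    stop_invalid("LOSO needs at least 2 subjects.")
  }
  tibble(
    held_out_subject = subjects,
    train = purrr::map(subjects, ~ which(matrix$subject_id != .x)),
    test = purrr::map(subjects, ~ which(matrix$subject_id == .x))
  )
}

#' Fit a classifier on a training fold and predict the test fold
#'
#' Features are standardized with training-fold statistics only (no
#' leakage); constant training columns get unit scale. Stochastic learners
#' (random forest) are made deterministic by the seed.
#'
#' @param spec A [classifier_spec()].
#' @param train,test Data frames with a `label` column and feature columns.
#' @param seed Optional integer seed.
#' @return Factor of predicted labels for the test rows, with the levels of
#'   the training labels.
#' @export
fit_predict <- function(spec, train, test, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  lv <- sort(unique(train$label))
  if (length(lv) < 2L) {
    abort("Training fold contains a single class.",
      class = "physioload_degenerate_fold"
    )
  }
  feats <- feature_columns(train)
  xtr <- as.matrix(train[, feats, drop = FALSE])
  xte <- as.matrix(test[, feats, drop = FALSE])
  mu <- colMeans(xtr)
  sds <- apply(xtr, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  xtr <- scale(xtr, center = mu, scale = sds)
  xte <- scale(xte, center = mu, scale = sds)
  ytr <- factor(train$label, levels = lv)
  with_seed_(seed, {
    pred <- switch(spec$kind,
      knn = class::knn(train = xtr, test = xte, cl = ytr, k = spec$k),
      svm = {
        fit <- e1071::svm(
          x = xtr, y = ytr, kernel = "polynomial",
          degree = spec$degree, coef0 = spec$coef0, cost = spec$cost,
          scale = FALSE
        )
        predict(fit, xte)
      },
      dt = {
        df_tr <- data.frame(label = ytr, xtr, check.names = FALSE)
        df_te <- data.frame(xte, check.names = FALSE)
        fit <- rpart::rpart(label ~ .,
          data = df_tr, method = "class",
          parms = list(split = "gini"),
          control = rpart::rpart.control(
            cp = 0, minsplit = 2, minbucket = 1, xval = 0
          )
        )
        factor(predict(fit, df_te, type = "class"), levels = lv)
      },
      rf = {
        fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = spec$ntree)
        predict(fit, xte)
      }
    )
    factor(as.character(pred), levels = lv)
  })
}

#' Classification metrics from a confusion matrix
#'
#' Exactly the four standard formulas: accuracy `(TP+TN)/(TP+FP+TN+FN)`,
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1, the harmonic mean of
#' precision and recall. Division-by-zero cases return 0 with
#' `zero_division = TRUE` rather than `NaN`.
#'
#' @param tp,tn,fp,fn Nonnegative confusion-matrix counts with positive sum.
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`
#'   and `zero_division`.
#' @examples
#' compute_metrics(3, 2, 1, 2)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("Counts must be nonnegative integers.")
  }
  if (sum(counts) == 0) {
    stop_invalid("At least one count must be positive.")
  }
  flag <- FALSE
  accuracy <- (tp + tn) / (tp + fp + tn + fn)
  precision <- if (tp + fp > 0) {
    tp / (tp + fp)
  } else {
    flag <- TRUE
    0
  }
  recall <- if (tp + fn > 0) {
    tp / (tp + fn)
  } else {
    flag <- TRUE
    0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    flag <- TRUE
    0
  }
  tibble(
    accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
    zero_division = flag
  )
}

#' Run a leave-one-subject-out classification experiment
#'
#' Evaluates a classifier under LOSO validation: for each fold the model is
#' trained on all other subjects' windows and tested on the held-out
#' subject's windows, treating `expert` as the positive class. Per-fold
#' confusion counts and metrics are reported along with two aggregates:
#' the mean of the per-fold accuracy/F1 (`mean-over-folds`) and the metrics
#' of the pooled confusion counts (`pooled-windows`). `aggregation` selects
#' which of the two [glance()] reports.
#'
#' @param matrix A [assemble_matrix()] tibble.
#' @param spec A [classifier_spec()] (default KNN, k = 5).
#' @param aggregation `"mean-over-folds"` (default) or `"pooled-windows"`.
#' @param features Optional character vector restricting the feature
#'   columns (e.g. a LASSO selection); `NULL` uses all.
#' @param positive Positive class label (default `"expert"`).
#' @param seed Optional integer seed, applied per fold.
#' @return A list of class `evaluation_report` with elements `per_fold`
#'   (tibble), `aggregate` (tibble with both aggregation modes),
#'   `aggregation`, `spec`, `n_rows`, `seed` and `config_hash`.
#' @export
run_experiment <- function(matrix, spec = classifier_spec("knn"),
                           aggregation = c("mean-over-folds", "pooled-windows"),
                           features = NULL, positive = "expert", seed = NULL) {
  aggregation <- match.arg(aggregation)
  keep <- c(intersect(meta_columns(), names(matrix)))
  if (!is.null(features)) {
    missing <- setdiff(features, names(matrix))
    if (length(missing)) {
      stop_invalid(paste0(
        "Unknown feature(s): ", paste(missing, collapse = ", ")
      ))
    }
    matrix <- matrix[, c(keep, features), drop = FALSE]
  }
  folds <- loso_folds(matrix)
  fold_rows <- purrr::map(seq_len(nrow(folds)), function(i) {
    train <- matrix[folds$train[[i]], , drop = FALSE]
    test <- matrix[folds$test[[i]], , drop = FALSE]
    if (length(unique(train$label)) < 2L) {
      warn(sprintf(
        "Skipping fold %s: training data has a single class.",
        folds$held_out_subject[i]
      ))
      return(NULL)
    }
    pred <- fit_predict(spec, train, test, seed = seed)
    truth <- test$label
    tp <- sum(pred == positive & truth == positive)
    tn <- sum(pred != positive & truth != positive)
    fp <- sum(pred == positive & truth != positive)
    fn <- sum(pred != positive & truth == positive)
    bind_cols(
      tibble(
        held_out_subject = folds$held_out_subject[i],
        tp = tp, tn = tn, fp = fp, fn = fn
      ),
      compute_metrics(tp, tn, fp, fn)
    )
  })
  per_fold <- bind_rows(fold_rows)
  if (nrow(per_fold) == 0L) {
    abort("All folds were degenerate; nothing to evaluate.",
      class = "physioload_degenerate_fold"
    )
  }
  pooled <- compute_metrics(
    sum(per_fold$tp), sum(per_fold$tn), sum(per_fold$fp), sum(per_fold$fn)
  )
  aggregate <- bind_rows(
    tibble(
      aggregation = "mean-over-folds",
      accuracy = mean(per_fold$accuracy), f1 = mean(per_fold$f1)
    ),
    tibble(
      aggregation = "pooled-windows",
      accuracy = pooled$accuracy, f1 = pooled$f1
    )
  )
  report <- list(
    per_fold = per_fold,
    aggregate = aggregate,
    aggregation = aggregation,
    spec = spec,
    n_rows = nrow(matrix),
    positive = positive,
    seed = seed,
    config_hash = rlang::hash(list(spec, aggregation, features, seed))
  )
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  agg <- x$aggregate[x$aggregate$aggregation == x$aggregation, ]
  cat(sprintf(
    "<evaluation_report> %s, %d folds, %d rows\n  %s: accuracy %.4f, F1 %.4f\n",
    x$spec$kind, nrow(x$per_fold), x$n_rows,
    x$aggregation, agg$accuracy, agg$f1
  ))
  invisible(x)
}

#' Project a feature matrix to 2-D with t-SNE
#'
#' Embeds the (standardized) feature rows in two dimensions with t-SNE
#' (default: perplexity 30, 10,000 iterations, learning rate 10) and scores
#' the class separability of the embedding with the mean silhouette width
#' of the true labels. When there are fewer than `3 * perplexity + 1` rows
#' the perplexity is reduced automatically with a warning.
#'
#' @param matrix A [assemble_matrix()] tibble.
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter Number of gradient iterations (default 10000).
#' @param eta Learning rate (default 10).
#' @param theta Barnes-Hut accuracy trade-off (0 = exact; default 0.5).
#' @param seed Optional integer seed for a reproducible embedding.
#' @return A tibble of class `tsne_embedding` with columns `dim1`, `dim2`,
#'   `subject_id`, `label`; the mean silhouette width is attached as
#'   attribute `"silhouette"`.
#' @export
tsne_embed <- function(matrix, perplexity = 30, max_iter = 10000, eta = 10,
                       theta = 0.5, seed = NULL) {
  feats <- feature_columns(matrix)
  x <- scale(as.matrix(matrix[, feats, drop = FALSE]))
  x[, !is.finite(colSums(x))] <- 0
  n <- nrow(x)
  if (n < 4L) stop_invalid("t-SNE needs at least 4 rows.")
  if (n - 1 < 3 * perplexity) {
    perplexity <- floor((n - 1) / 3)
    warn(sprintf("Too few rows for the requested perplexity; reduced to %d.", perplexity))
  }
  emb <- with_seed_(seed, {
    Rtsne::Rtsne(x,
      dims = 2, perplexity = perplexity, max_iter = max_iter,
      eta = eta, theta = theta, pca = FALSE, check_duplicates = FALSE,
      verbose = FALSE
    )$Y
  })
  out <- tibble(
    dim1 = emb[, 1], dim2 = emb[, 2],
    subject_id = if ("subject_id" %in% names(matrix)) matrix$subject_id else NA_character_,
    label = matrix$label
  )
  cl <- as.integer(factor(matrix$label))
  sil <- if (length(unique(cl)) > 1L) {
    mean(cluster::silhouette(cl, stats::dist(emb))[, "sil_width"])
  } else {
    NA_real_
  }
  attr(out, "silhouette") <- sil
  class(out) <- c("tsne_embedding", class(out))
  out
}
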