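#' Rank features by LASSO regression coefficients
#'
#' Fits an L1-penalized regression of the binary class label (expert = 1,
#' novice = 0) on the feature matrix and reports the coefficient of every
#' feature on the standardized scale, so magnitudes are comparable across
#' features. Features are standardized internally (zero mean, unit
#' variance); constant columns are dropped with a warning. The penalty
#' strength is either a fixed value or chosen by 5-fold cross-validation
#' (`penalty = "cv"`, using the conservative one-standard-error rule, which
#' suits a selector whose job is to zero out uninformative features). The
#' regression is linear by default; a logistic variant is available via
#' `family = "binomial"`.
#'
#' @param data A [assemble_matrix()] tibble, or any data frame with a
#'   `label` column and numeric feature columns (metadata columns
#'   `subject_id`, `window_id`, `start`, `end`, `modality` are ignored).
#' @param penalty `"cv"` or a fixed nonnegative lambda.
#' @param family `"gaussian"` (penalized linear regression, default) or
#'   `"binomial"`.
#' @param positive Label treated as 1 (default `"expert"`).
#' @param seed Optional seed (cross-validation folds are deterministic
#'   anyway: rows are cycled through the 5 folds in order).
#' @return A tibble of class `lasso_ranking` with columns `feature`,
#'   `coefficient`, `abs_coefficient`, sorted by decreasing magnitude
#'   (ties broken by feature name); the chosen lambda is attached as
#'   attribute `"penalty_strength"`.
#' @examples
#' d <- tibble::tibble(
#'   label = rep(c("expert", "novice"), each = 20),
#'   f1 = rep(c(1, 0), each = 20) + rnorm(40, sd = 0.1),
#'   f2 = rnorm(40)
#' )
#' lasso_rank(d, penalty = 0.05)
#' @export
lasso_rank <- function(data, penalty = "cv", family = c("gaussian", "binomial"),
                       positive = "expert", seed = NULL) {
  family <- match.arg(family)
  if (!"label" %in% names(data)) stop_invalid("`data` must have a `label` column.")
  y <- as.integer(data$label == positive)
  if (length(unique(y)) < 2L) {
    stop_invalid("`label` must contain both classes.")
  }
  if (min(table(y)) < 2L) {
    stop_invalid("Need at least 2 rows per class.")
  }
  feats <- feature_columns(data)
  x <- as.matrix(data[, feats, drop = FALSE])
  # population-SD standardization (as glmnet does internally); unlike the
  # sample SD it is invariant under duplicating every row
  mu <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, mu)^2))
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warn(paste0(
      "Dropping constant feature column(s): ",
      paste(feats[constant], collapse = ", ")
    ))
    x <- x[, !constant, drop = FALSE]
    feats <- feats[!constant]
  }
  if (ncol(x) == 0L) stop_invalid("No non-constant features to rank.")
  xs <- scale(x, center = mu[!constant], scale = sds[!constant])
  with_seed_(seed, {
    if (identical(penalty, "cv")) {
      foldid <- rep_len(1:5, nrow(xs))
      cvfit <- glmnet::cv.glmnet(xs, y,
        family = family, alpha = 1,
        standardize = FALSE, foldid = foldid
      )
      lambda <- cvfit$lambda.1se
      fit <- cvfit$glmnet.fit
    } else {
      if (!is.numeric(penalty) || penalty < 0) {
        stop_invalid("`penalty` must be \"cv\" or a nonnegative number.")
      }
      lambda <- penalty
      fit <- glmnet::glmnet(xs, y,
        family = family, alpha = 1,
        standardize = FALSE
      )
    }
    co <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))[-1]
    out <- tibble(
      feature = feats,
      coefficient = co,
      abs_coefficient = abs(co)
    )
    out <- out[order(-out$abs_coefficient, out$feature), ]
    attr(out, "penalty_strength") <- lambda
    attr(out, "family") <- family
    class(out) <- c("lasso_ranking", class(out))
    out
  })
}

#' Select features whose LASSO coefficient exceeds a threshold
#'
#' Keeps the features with `|coefficient| > threshold` (strict inequality),
#' ordered by decreasing magnitude with ties broken alphabetically. The
#' default cutoff of 0.01 separates discriminative features from noise;
#' `threshold = 0` selects exactly the non-zero-coefficient set. An empty
#' selection triggers a warning so the caller can fall back to the full
#' feature set.
#'
#' @param ranking A [lasso_rank()] result.
#' @param threshold Magnitude cutoff (default 0.01).
#' @return Character vector of selected feature names.
#' @examples
#' r <- tibble::tibble(
#'   feature = c("a", "b", "c"),
#'   coefficient = c(0.90, 0.005, -0.02)
#' )
#' r$abs_coefficient <- abs(r$coefficient)
#' class(r) <- c("lasso_ranking", class(r))
#' apply_threshold(r) # "a" "c"
#' @export
apply_threshold <- function(ranking, threshold = 0.01) {
  if (!all(c("feature", "abs_coefficient") %in% names(ranking))) {
    stop_invalid("`ranking` must have `feature` and `abs_coefficient` columns.")
  }
  sel <- ranking[ranking$abs_coefficient > threshold, , drop = FALSE]
  sel <- sel[order(-sel$abs_coefficient, sel$feature), ]
  if (nrow(sel) == 0L) {
    warn("No feature exceeds the threshold; selection is empty.",
      class = "physioload_empty_selection"
    )
    return(character(0))
  }
  sel$feature
}
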