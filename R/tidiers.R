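# broom-style tidiers for the package's result objects.

#' Tidy a LASSO ranking
#'
#' @param x A [lasso_rank()] result.
#' @param ... Unused.
#' @return A tibble with `feature`, `coefficient`, `abs_coefficient`.
#' @method tidy lasso_ranking
#' @export
tidy.lasso_ranking <- function(x, ...) {
  as_tibble(unclass(x)[c("feature", "coefficient", "abs_coefficient")])
}

#' @rdname tidy.lasso_ranking
#' @method glance lasso_ranking
#' @export
glance.lasso_ranking <- function(x, ...) {
  tibble(
    penalty_strength = attr(x, "penalty_strength"),
    family = attr(x, "family"),
    n_features = nrow(x),
    n_nonzero = sum(x$abs_coefficient > 0)
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-fold confusion counts and metrics; `glance()`
#' the one-row aggregate for the report's aggregation mode.
#'
#' @param x An [run_experiment()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  x$per_fold
}

#' @rdname tidy.evaluation_report
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  agg <- x$aggregate[x$aggregate$aggregation == x$aggregation, ]
  tibble(
    classifier = x$spec$kind,
    aggregation = x$aggregation,
    n_folds = nrow(x$per_fold),
    n_rows = x$n_rows,
    accuracy = agg$accuracy,
    f1 = agg$f1
  )
}

#' Tidy a t-SNE embedding
#'
#' @param x A [tsne_embed()] result.
#' @param ... Unused.
#' @return The embedding tibble (`tidy`) or a one-row summary with the
#'   silhouette score (`glance`).
#' @method tidy tsne_embedding
#' @export
tidy.tsne_embedding <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.tsne_embedding
#' @method glance tsne_embedding
#' @export
glance.tsne_embedding <- function(x, ...) {
  tibble(n = nrow(x), silhouette = attr(x, "silhouette"))
}
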