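#' Tidy a chaos evaluation
#'
#' @param x A `chaos_eval` from [global_metrics()].
#' @param ... Unused.
#' @return Per-class tibble of support, precision, recall and F1.
#' @export
tidy.chaos_eval <- function(x, ...) x$per_class

#' One-row summary of a chaos evaluation
#'
#' @param x A `chaos_eval`.
#' @param ... Unused.
#' @return One-row tibble of macro and weighted precision/recall/F1.
#' @export
glance.chaos_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    macro_precision = x$macro$precision, macro_recall = x$macro$recall,
    macro_f1 = x$macro$f1,
    weighted_precision = x$weighted$precision,
    weighted_recall = x$weighted$recall, weighted_f1 = x$weighted$f1,
    n_excluded_classes = length(x$excluded_classes)
  )
}

#' Tidy a fitted chaos random forest
#'
#' @param x A `chaos_rf`.
#' @param ... Unused.
#' @return Tibble of per-feature impurity importance (when recorded) or
#'   the feature list.
#' @export
tidy.chaos_rf <- function(x, ...) {
  imp <- x$fit$variable.importance
  if (is.null(imp)) {
    return(tibble::tibble(feature = x$features, importance = NA_real_))
  }
  tibble::tibble(feature = names(imp), importance = unname(imp))
}

#' @export
glance.chaos_rf <- function(x, ...) {
  tibble::tibble(feature_set = x$feature_set, n_features = length(x$features),
                 n_trees = x$n_trees, oob_error = x$fit$prediction.error)
}

#' Tidy a trained chaos CNN (training history)
#'
#' @param x A `chaos_cnn`.
#' @param ... Unused.
#' @return Tibble: epoch, train_loss, val_accuracy.
#' @export
tidy.chaos_cnn <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_accuracy = numeric())
}

#' @export
glance.chaos_cnn <- function(x, ...) {
  tibble::tibble(
    param_count = x$param_count, trained = x$trained,
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    val_accuracy = x$val_accuracy %||% NA_real_
  )
}

#' Tidy a LOPO cross-validation result
#'
#' @param x A `chaos_lopo`.
#' @param ... Unused.
#' @return The pooled per-class metric tibble.
#' @export
tidy.chaos_lopo <- function(x, ...) tidy(x$report)

#' @export
glance.chaos_lopo <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_folds = x$n_folds), glance(x$report))
}
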