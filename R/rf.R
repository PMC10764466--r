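#' Train a random-forest chaos classifier
#'
#' Fits a 1000-tree probability forest on segment-level acoustic
#' features: either the 3-feature volume baseline (`"f3"`: mean RMSE,
#' RMSE standard deviation, peak amplitude) or the 53-feature acoustic
#' set (`"f53"`). Training is deterministic given `seed`.
#'
#' @param data Feature tibble from [segment_features()] including a
#'   `chaos_level` column.
#' @param feature_set `"f53"` or `"f3"`.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed.
#' @return A `chaos_rf` model object.
#' @export
train_rf <- function(data, feature_set = c("f53", "f3"), n_trees = 1000L,
                     seed = 1L) {
  feature_set <- match.arg(feature_set)
  if (n_trees < 1) abort("`n_trees` must be at least 1.")
  feats <- rf_feature_names(feature_set)
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "Feature table does not match feature set '%s' (expected %d features, %d missing, e.g. %s).",
      feature_set, length(feats), length(missing), missing[1]))
  }
  assert_columns(data, "chaos_level", "training data")
  y <- factor(data$chaos_level, levels = CHAOS_LEVELS)
  if (length(unique(data$chaos_level)) < 2) {
    abort("Training labels contain a single class; at least 2 are required.")
  }
  fit <- ranger::ranger(
    x = as.data.frame(data[feats]), y = y,
    num.trees = n_trees, probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(fit = fit, feature_set = feature_set, features = feats,
                 n_trees = n_trees, seed = seed),
            class = "chaos_rf")
}

rf_feature_names <- function(feature_set) {
  if (feature_set == "f53") feature53_names() else
    c("mean_rmse", "sd_rmse", "peak_amplitude")
}

#' @export
print.chaos_rf <- function(x, ...) {
  cat(sprintf("<chaos_rf> %s (%d features), %d trees, OOB error %.3f\n",
              x$feature_set, length(x$features), x$n_trees,
              x$fit$prediction.error))
  invisible(x)
}

#' Predict chaos probabilities with a trained random forest
#'
#' @param object A `chaos_rf` model.
#' @param newdata Feature tibble (or segment tibble with `samples`, in
#'   which case features are extracted first).
#' @param ... Unused.
#' @return Tibble with keys (when present), `p0`..`p3` and
#'   `predicted_level` (argmax, ties to the lowest level).
#' @export
predict.chaos_rf <- function(object, newdata, ...) {
  if (!all(object$features %in% names(newdata)) && "samples" %in% names(newdata)) {
    newdata <- segment_features(newdata, set = object$feature_set)
  }
  assert_columns(newdata, object$features, "feature table")
  raw <- predict(object$fit, data = as.data.frame(newdata[object$features]),
                 num.threads = 1)$predictions
  probs <- matrix(0, nrow(raw), 4,
                  dimnames = list(NULL, paste0("p", CHAOS_LEVELS)))
  probs[, paste0("p", colnames(raw))] <- raw
  keep <- intersect(c("participant_id", "segment_index", "chaos_level"),
                    names(newdata))
  out <- dplyr::bind_cols(newdata[keep], tibble::as_tibble(probs))
  out$predicted_level <- apply(probs, 1, argmax_lowest)
  out
}
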