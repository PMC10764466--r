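#' Attach model-ready representations to a labeled segment table
#'
#' Precomputes, once per segment, everything the three classifiers need:
#' the 53 acoustic feature columns (a superset of the 3 volume features)
#' and the list of 2-s log-mel patches. Model factories then train and
#' predict without touching the waveforms again.
#'
#' @param segments Labeled segment tibble (`participant_id`,
#'   `segment_index`, `samples`, `chaos_level`).
#' @return The input tibble plus 53 feature columns and a `patches`
#'   list-column.
#' @export
prepare_chaos_data <- function(segments) {
  assert_columns(segments, c("participant_id", "segment_index", "samples",
                             "chaos_level"), "segment table")
  feats <- do.call(rbind, lapply(segments$samples, extract_features53))
  out <- dplyr::bind_cols(segments, tibble::as_tibble(feats))
  out$patches <- lapply(segments$samples, logmel_patches)
  out
}

## expand a prepared table (patches list-column) into a patch-level tibble
expand_patches <- function(data) {
  if ("patch" %in% names(data)) return(data)
  if (!"patches" %in% names(data)) return(segment_patches(data))
  keep <- intersect(c("participant_id", "segment_index", "chaos_level"),
                    names(data))
  n_per <- vapply(data$patches, length, integer(1))
  out <- data[rep(seq_len(nrow(data)), n_per), keep]
  out$patch_index <- unlist(lapply(n_per, seq_len)) - 1L
  out$patch <- unlist(data$patches, recursive = FALSE)
  tibble::as_tibble(out)
}

#' Model factories for cross-validation
#'
#' A model factory is a `function(train_data, seed)` returning a fitted
#' model whose `predict()` method accepts the same kind of data. These
#' constructors build factories for the three chaos classifiers over
#' prepared segment tables (see [prepare_chaos_data()]).
#'
#' @param feature_set `"f53"` or `"f3"` for the random-forest factories.
#' @param n_trees Trees in the forest (default 1000).
#' @param config A [cnn_config()] for the CNN factory; its seed is
#'   replaced by the fold seed.
#' @return A factory function.
#' @export
rf_factory <- function(feature_set = c("f53", "f3"), n_trees = 1000L) {
  feature_set <- match.arg(feature_set)
  function(train_data, seed = 1L) {
    train_rf(train_data, feature_set = feature_set, n_trees = n_trees,
             seed = seed)
  }
}

#' @rdname rf_factory
#' @export
cnn_factory <- function(config = cnn_config()) {
  function(train_data, seed = 1L) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    train_cnn(expand_patches(train_data), cfg)
  }
}

#' Build a class-balanced training set
#'
#' Samples an equal time budget per chaos level from the non-test
#' participants. Level 0 (no chaos: silence) is the only level sampled
#' with repetition: every available level-0 segment is included at least
#' once and the remainder of the budget is drawn with replacement —
#' repeating silence does not change the nature of the class. For the
#' other levels the budget is drawn without replacement, and a pool
#' smaller than the budget is an explicit shortfall error.
#'
#' @param dataset Labeled segment tibble.
#' @param budget_hours_per_class Hours per chaos level (the deployed
#'   condition is 10 h per level, 40 h total).
#' @param test_participant Participant excluded from sampling (`NULL`
#'   for none).
#' @param repetition_levels Levels allowed to repeat (default `0`).
#' @param seed Integer seed.
#' @return Training tibble (rows may repeat for repetition levels), with
#'   a `manifest` attribute summarising counts per level.
#' @export
make_balanced_trainset <- function(dataset, budget_hours_per_class,
                                   test_participant = NULL,
                                   repetition_levels = 0L, seed = 1L) {
  assert_columns(dataset, c("participant_id", "chaos_level"), "dataset")
  pool <- dataset[!dataset$participant_id %in% test_participant, ]
  needed <- as.integer(round(budget_hours_per_class * SEGMENTS_PER_HOUR))
  if (needed < 1) abort("Per-class budget is below one segment.")
  with_seed(seed, {
    parts <- lapply(CHAOS_LEVELS, function(lv) {
      rows <- which(pool$chaos_level == lv)
      if (lv %in% repetition_levels) {
        if (length(rows) >= needed) {
          rows[sample.int(length(rows), needed)]
        } else {
          c(rows, rows[sample.int(length(rows), needed - length(rows),
                                  replace = TRUE)])
        }
      } else {
        if (length(rows) < needed) {
          abort(sprintf(
            "Shortfall for chaos level %d: %.2f h available, %.2f h needed (non-repetition class).",
            lv, length(rows) / SEGMENTS_PER_HOUR, budget_hours_per_class))
        }
        rows[sample.int(length(rows), needed)]
      }
    })
    out <- pool[unlist(parts), ]
    attr(out, "manifest") <- tibble::tibble(
      chaos_level = CHAOS_LEVELS,
      n_available = vapply(CHAOS_LEVELS, function(lv) sum(pool$chaos_level == lv), numeric(1)),
      n_sampled = needed,
      with_repetition = CHAOS_LEVELS %in% repetition_levels
    )
    out
  })
}

#' Largest feasible per-class training budget
#'
#' The deployed per-class budget (10 h in the 40-h condition) was set by
#' the scarcest non-repetition class after removing the test participant.
#' This helper generalises that rule: for every possible test participant
#' it computes the hours available per non-repetition class among the
#' remaining participants, and returns the minimum — the largest budget
#' every LOPO fold can satisfy without sampling with repetition.
#'
#' @param dataset Labeled segment tibble.
#' @param non_repetition_levels Levels that must not repeat (default
#'   `1:3`).
#' @return Budget in hours per class.
#' @export
max_balanced_budget <- function(dataset, non_repetition_levels = 1:3) {
  participants <- unique(dataset$participant_id)
  mins <- vapply(participants, function(pid) {
    pool <- dataset[dataset$participant_id != pid, ]
    min(vapply(non_repetition_levels,
               function(lv) sum(pool$chaos_level == lv), numeric(1)))
  }, numeric(1))
  min(mins) / SEGMENTS_PER_HOUR
}

#' Global multi-class performance metrics
#'
#' Per-class precision/recall/F1 from the 4x4 confusion matrix, plus the
#' macro (unweighted mean over classes) and weighted (class-support
#' weighted mean) aggregates. Classes absent from both truth and
#' prediction are excluded from the macro average rather than scored 0;
#' the excluded classes are recorded on the result.
#'
#' @param y_true,y_pred Equal-length integer vectors over the chaos
#'   levels 0-3.
#' @param levels Class universe (default `0:3`).
#' @return A `chaos_eval` object: `per_class` tibble, `macro` and
#'   `weighted` one-row tibbles, `confusion` matrix, `excluded_classes`.
#' @export
global_metrics <- function(y_true, y_pred, levels = CHAOS_LEVELS) {
  stopifnot(length(y_true) == length(y_pred))
  tf <- factor(y_true, levels = levels)
  pf <- factor(y_pred, levels = levels)
  confusion <- table(truth = tf, prediction = pf)

  support <- rowSums(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- support - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble::tibble(
    chaos_level = levels, support = as.integer(support),
    precision = as.numeric(precision), recall = as.numeric(recall),
    f1 = as.numeric(f1)
  )
  present <- support > 0 | colSums(confusion) > 0
  macro <- tibble::tibble(
    precision = mean(precision[present]),
    recall = mean(recall[present]),
    f1 = mean(f1[present])
  )
  w <- support / sum(support)
  weighted <- tibble::tibble(
    precision = sum(w * precision),
    recall = sum(w * recall),
    f1 = sum(w * f1)
  )
  structure(
    list(per_class = per_class, macro = macro, weighted = weighted,
         confusion = confusion, excluded_classes = levels[!present],
         n = length(y_true)),
    class = "chaos_eval"
  )
}

#' @export
print.chaos_eval <- function(x, ...) {
  cat(sprintf("<chaos_eval> n = %d\n", x$n))
  cat(sprintf("  macro    P %.3f  R %.3f  F1 %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("  weighted P %.3f  R %.3f  F1 %.3f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  if (length(x$excluded_classes) > 0) {
    cat("  macro average excludes absent class(es):",
        paste(x$excluded_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Participant-specific weighted scores
#'
#' Weighted precision/recall/F1 computed within each participant's test
#' predictions only — the per-participant scores paired model comparisons
#' are run on.
#'
#' @param predictions Tibble with `participant_id`, `chaos_level`
#'   (truth) and `predicted_level`.
#' @return Tibble: one row per participant with `n`, `weighted_precision`,
#'   `weighted_recall`, `weighted_f1`.
#' @export
participant_weighted_scores <- function(predictions) {
  assert_columns(predictions, c("participant_id", "chaos_level", "predicted_level"),
                 "prediction table")
  predictions |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      ev <- global_metrics(df$chaos_level, df$predicted_level)
      tibble::tibble(n = nrow(df),
                     weighted_precision = ev$weighted$precision,
                     weighted_recall = ev$weighted$recall,
                     weighted_f1 = ev$weighted$f1)
    }) |>
    dplyr::ungroup()
}

#' Paired comparison of two models across participants
#'
#' Two-sided paired t-test on participant-specific weighted F1 scores.
#' Identical score vectors give `t = 0, p = 1`; a constant non-zero
#' difference (zero variance) is flagged as degenerate instead of
#' reporting an infinite statistic.
#'
#' @param scores_a,scores_b Either numeric vectors aligned by participant
#'   or tibbles from [participant_weighted_scores()] (joined on
#'   `participant_id`, compared on `weighted_f1`).
#' @return One-row tibble: `estimate` (mean A - B), `t`, `df`, `p_value`,
#'   `degenerate`.
#' @export
paired_model_test <- function(scores_a, scores_b) {
  if (is.data.frame(scores_a)) {
    joined <- dplyr::inner_join(scores_a, scores_b, by = "participant_id",
                                suffix = c("_a", "_b"))
    a <- joined$weighted_f1_a
    b <- joined$weighted_f1_b
  } else {
    a <- as.numeric(scores_a)
    b <- as.numeric(scores_b)
  }
  if (length(a) != length(b) || length(a) < 2) {
    abort("Paired comparison needs the same >= 2 participants in both models.")
  }
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(estimate = 0, t = 0, df = length(d) - 1,
                            p_value = 1, degenerate = FALSE))
    }
    warning("Zero-variance non-zero paired differences: t statistic undefined.")
    return(tibble::tibble(estimate = mean(d), t = NA_real_,
                          df = length(d) - 1, p_value = NA_real_,
                          degenerate = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 degenerate = FALSE)
}

#' Leave-one-participant-out cross-validation
#'
#' One fold per participant: a class-balanced training set is sampled
#' from all other participants, a model is fitted by the factory, and the
#' held-out participant's segments are predicted. Fold predictions are
#' pooled for global metrics; per-participant weighted scores are kept
#' for paired comparisons.
#'
#' @param dataset Prepared labeled segment tibble
#'   (see [prepare_chaos_data()]).
#' @param model_factory A factory from [rf_factory()] / [cnn_factory()].
#' @param budget_hours_per_class Per-class training budget in hours.
#' @param seed Integer seed driving sampling and model fits.
#' @return A `chaos_lopo` object: pooled `predictions` tibble, pooled
#'   `report` ([global_metrics()]), `per_participant` weighted scores.
#' @export
lopo_cv <- function(dataset, model_factory, budget_hours_per_class,
                    seed = 1L) {
  assert_columns(dataset, c("participant_id", "segment_index", "chaos_level"),
                 "dataset")
  participants <- sort(unique(dataset$participant_id))
  if (length(participants) < 2) {
    abort("LOPO cross-validation needs at least 2 participants.")
  }
  folds <- lapply(seq_along(participants), function(i) {
    pid <- participants[i]
    train <- make_balanced_trainset(
      dataset, budget_hours_per_class, test_participant = pid,
      seed = derive_seed(seed, i)
    )
    if (pid %in% train$participant_id) {
      abort(sprintf("Leakage: test participant %s appears in fold training data.", pid))
    }
    model <- model_factory(train, seed = derive_seed(seed, 1000L + i))
    test <- dataset[dataset$participant_id == pid, ]
    preds <- predict(model, test)
    preds$chaos_level <- test$chaos_level[
      match(segment_key(preds$participant_id, preds$segment_index),
            segment_key(test$participant_id, test$segment_index))]
    preds
  })
  predictions <- dplyr::bind_rows(folds)
  structure(
    list(predictions = predictions,
         report = global_metrics(predictions$chaos_level,
                                 predictions$predicted_level),
         per_participant = participant_weighted_scores(predictions),
         n_folds = length(participants), seed = seed,
         budget_hours_per_class = budget_hours_per_class),
    class = "chaos_lopo"
  )
}

#' @export
print.chaos_lopo <- function(x, ...) {
  cat(sprintf("<chaos_lopo> %d folds, %.2g h/class budget\n",
              x$n_folds, x$budget_hours_per_class))
  print(x$report)
  invisible(x)
}

#' Split an annotated dataset into Cry and Non-cry evaluation sets
#'
#' Segments whose sound-event prediction table contains a cry-like class
#' form the Cry set; the rest form the Non-cry set. Within the Cry set,
#' segments the model predicted as level 0 are dropped before evaluation
#' (too few to score reliably). The two sets partition the dataset before
#' that drop.
#'
#' @param dataset Labeled segment tibble.
#' @param sound_events Sound-event prediction tibble (`participant_id`,
#'   `segment_index`, `class_name`).
#' @param model_predictions Model prediction tibble with
#'   `predicted_level`.
#' @param group_map Group map carrying `cry_like` flags.
#' @return List: `cry` and `non_cry` tibbles of joined truth/prediction
#'   rows, and `n_cry_dropped` (predicted-level-0 cry segments removed).
#' @export
split_cry_noncry <- function(dataset, sound_events, model_predictions,
                             group_map = build_group_map(default_class_metadata())) {
  cry_classes <- group_map$class_name[group_map$cry_like]
  cry_keys <- sound_events |>
    dplyr::filter(.data$class_name %in% cry_classes) |>
    dplyr::distinct(.data$participant_id, .data$segment_index)
  joined <- dataset |>
    dplyr::select("participant_id", "segment_index", "chaos_level") |>
    dplyr::inner_join(
      model_predictions[c("participant_id", "segment_index", "predicted_level")],
      by = c("participant_id", "segment_index")
    ) |>
    dplyr::mutate(is_cry = segment_key(.data$participant_id, .data$segment_index) %in%
                    segment_key(cry_keys$participant_id, cry_keys$segment_index))
  cry <- joined[joined$is_cry, ]
  dropped <- sum(cry$predicted_level == 0L)
  list(
    cry = cry[cry$predicted_level != 0L, setdiff(names(cry), "is_cry")],
    non_cry = joined[!joined$is_cry, setdiff(names(joined), "is_cry")],
    n_cry_dropped = dropped
  )
}

#' Training-data ablation harness
#'
#' Re-runs balanced-sample -> LOPO-CV at a grid of training-set sizes
#' (total hours across the four classes), several seeded repetitions per
#' size: the default deployed grid is 40/20/10/5 h x 3 runs = 12
#' experiments. Folds are shared across sizes within a run (same run
#' seed) for variance reduction. Sizes the dataset cannot support are
#' skipped with a warning.
#'
#' @param dataset Prepared labeled segment tibble.
#' @param model_factory A model factory.
#' @param sizes_hours Total balanced training hours per experiment
#'   (default `c(40, 20, 10, 5)`).
#' @param runs_per_size Seeded repetitions per size (default 3).
#' @param seed Integer seed.
#' @return A `chaos_ablation` tibble: one row per run x size with
#'   pooled macro/weighted metrics.
#' @export
run_ablation <- function(dataset, model_factory,
                         sizes_hours = c(40, 20, 10, 5),
                         runs_per_size = 3L, seed = 1L) {
  rows <- list()
  for (r in seq_len(runs_per_size)) {
    run_seed <- derive_seed(seed, r)
    for (s in sizes_hours) {
      res <- tryCatch(
        lopo_cv(dataset, model_factory, budget_hours_per_class = s / 4,
                seed = run_seed),
        error = function(e) {
          warning(sprintf("Ablation size %g h skipped in run %d: %s",
                          s, r, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size_hours = s, run = r, seed = run_seed,
        macro_precision = res$report$macro$precision,
        macro_recall = res$report$macro$recall,
        macro_f1 = res$report$macro$f1,
        weighted_precision = res$report$weighted$precision,
        weighted_recall = res$report$weighted$recall,
        weighted_f1 = res$report$weighted$f1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chaos_ablation", class(out))
  out
}

#' Summarise an ablation run per training size
#'
#' @param ablation A `chaos_ablation` tibble from [run_ablation()].
#' @return Tibble: per size, number of runs and mean macro/weighted F1.
#' @export
summarise_ablation <- function(ablation) {
  ablation |>
    dplyr::group_by(.data$size_hours) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     mean_macro_f1 = mean(.data$macro_f1),
                     mean_weighted_f1 = mean(.data$weighted_f1),
                     .groups = "drop") |>
    dplyr::arrange(.data$size_hours)
}
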