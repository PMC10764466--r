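#' Default sound-event class metadata table
#'
#' Ships an illustrative class-metadata table covering the everyday-sound
#' classes the detector's grouping examples use: class name, an annotation
#' quality estimate in `[0, 1]`, an exclusion flag for classes implausible
#' in infant-worn home recordings, the high/non-high chaos group, and the
#' vehicle-like / cry-like / babble-like flags the pruning heuristics
#' consult. In real deployments the full class list of the external
#' sound-event classifier is user-supplied configuration in the same
#' format.
#'
#' @return Tibble with columns `class_name`, `quality_estimate`,
#'   `excluded`, `chaos_group`, `vehicle_like`, `cry_like`, `babble_like`.
#' @export
default_class_metadata <- function() {
  path <- system.file("extdata", "class_metadata.csv", package = "chaoscope")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Build the chaos group map from class metadata
#'
#' Drops classes with a quality estimate at or below the threshold (33%
#' by default) and classes flagged as excluded; every retained class must
#' carry a high/non-high group assignment.
#'
#' @param class_table Class metadata tibble (see
#'   [default_class_metadata()]).
#' @param quality_threshold Classes with `quality_estimate <= threshold`
#'   are dropped (default 0.33).
#' @return Tibble mapping `class_name` to `chaos_group` plus the
#'   vehicle/cry/babble flags.
#' @export
build_group_map <- function(class_table, quality_threshold = 0.33) {
  assert_columns(class_table, c("class_name", "quality_estimate", "chaos_group"),
                 "class metadata")
  if (!"excluded" %in% names(class_table)) class_table$excluded <- FALSE
  for (flag in c("vehicle_like", "cry_like", "babble_like")) {
    if (!flag %in% names(class_table)) class_table[[flag]] <- FALSE
  }
  kept <- class_table[class_table$quality_estimate > quality_threshold &
                        !class_table$excluded, ]
  bad <- kept$class_name[is.na(kept$chaos_group) |
                           !kept$chaos_group %in% c("high", "non_high")]
  if (length(bad) > 0) {
    abort(sprintf("Class(es) without a valid chaos group assignment: %s.",
                  paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(kept[c("class_name", "chaos_group", "vehicle_like",
                           "cry_like", "babble_like")])
}

#' Keep the top-k predictions above the confidence floor
#'
#' Per segment, retains at most the `k` most confident predictions and
#' discards any prediction below the floor (0.01% confidence, i.e. `1e-4`
#' on the `[0, 1]` score scale).
#'
#' @param preds Prediction tibble (`participant_id`, `segment_index`,
#'   `class_name`, `confidence`).
#' @param k Maximum predictions kept per segment (default 10).
#' @param min_confidence Confidence floor; predictions strictly below it
#'   are dropped (default `1e-4`).
#' @return Filtered prediction tibble, sorted by descending confidence
#'   within segment.
#' @export
filter_topk_confidence <- function(preds, k = 10, min_confidence = 1e-4) {
  assert_columns(preds, c("participant_id", "segment_index", "class_name",
                          "confidence"), "prediction table")
  preds |>
    dplyr::filter(.data$confidence >= min_confidence) |>
    dplyr::group_by(.data$participant_id, .data$segment_index) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}

## join helper: attach group + flags; unmapped classes get NA group and
## FALSE flags (they can never trigger a candidate)
join_group_flags <- function(preds, group_map) {
  out <- dplyr::left_join(preds, group_map, by = "class_name")
  for (flag in c("vehicle_like", "cry_like", "babble_like")) {
    out[[flag]][is.na(out[[flag]])] <- FALSE
  }
  out
}

#' Disambiguate joint cry/babble predictions by loudness
#'
#' Crying has much higher energy than babbling. For any segment carrying
#' both a cry-like and a babble-like prediction: if any frame RMSE exceeds
#' 3x that participant's mean RMSE, the babble prediction is dropped
#' (the segment is loud, so crying is more plausible); otherwise the cry
#' prediction is dropped. Segments with only one of the two are unchanged.
#'
#' @param preds Prediction tibble.
#' @param audio_summary Per-segment summary from [segment_audio_summary()]
#'   (needs `max_rmse`).
#' @param stats Participant stats from [participant_mean_rmse()].
#' @param group_map Group map from [build_group_map()].
#' @param multiplier Loudness multiple separating cry from babble
#'   (default 3).
#' @return Pruned prediction tibble.
#' @export
prune_cry_babble <- function(preds, audio_summary, stats, group_map,
                             multiplier = 3) {
  flagged <- join_group_flags(preds, group_map)
  both <- flagged |>
    dplyr::group_by(.data$participant_id, .data$segment_index) |>
    dplyr::summarise(has_both = any(.data$cry_like) && any(.data$babble_like),
                     .groups = "drop") |>
    dplyr::filter(.data$has_both)
  if (nrow(both) == 0) return(preds)
  if (is.null(audio_summary) || is.null(stats)) {
    abort("Cry/babble pruning needs segment RMSE and participant stats.")
  }
  assert_columns(audio_summary, c("participant_id", "segment_index", "max_rmse"),
                 "audio summary")
  assert_columns(stats, c("participant_id", "mean_rmse"), "participant stats")
  info <- both |>
    dplyr::left_join(audio_summary, by = c("participant_id", "segment_index")) |>
    dplyr::left_join(stats, by = "participant_id")
  if (any(is.na(info$max_rmse)) || any(is.na(info$mean_rmse))) {
    abort("Missing RMSE statistics for segment(s) with joint cry/babble predictions.")
  }
  info$loud <- info$max_rmse > multiplier * info$mean_rmse
  flagged |>
    dplyr::left_join(info[c("participant_id", "segment_index", "loud")],
                     by = c("participant_id", "segment_index")) |>
    dplyr::filter(is.na(.data$loud) |
                    !((.data$loud & .data$babble_like) |
                        (!.data$loud & .data$cry_like))) |>
    dplyr::select(dplyr::all_of(names(preds)))
}

#' Drop vehicle predictions on white-noise-like segments
#'
#' White-noise machines are commonly confused with vehicles by everyday
#' sound classifiers. If a segment looks like unvoiced noise — all its
#' spectral flatness values exceed `1e-4`, or its zero-crossing count lies
#' in `[1000, 4000]` — any vehicle-like prediction on it is removed.
#' Other predictions on the segment are untouched.
#'
#' @param preds Prediction tibble.
#' @param audio_summary Per-segment summary from [segment_audio_summary()]
#'   (needs `all_flatness_above` and `zero_crossings`).
#' @param group_map Group map from [build_group_map()].
#' @param zc_band Zero-crossing band flagging unvoiced noise
#'   (default `c(1000, 4000)`).
#' @return Pruned prediction tibble.
#' @export
prune_whitenoise_vehicle <- function(preds, audio_summary, group_map,
                                     zc_band = c(1000, 4000)) {
  assert_columns(audio_summary,
                 c("participant_id", "segment_index", "all_flatness_above",
                   "zero_crossings"), "audio summary")
  flagged <- join_group_flags(preds, group_map) |>
    dplyr::left_join(
      audio_summary[c("participant_id", "segment_index", "all_flatness_above",
                      "zero_crossings")],
      by = c("participant_id", "segment_index")
    )
  noisy <- !is.na(flagged$all_flatness_above) &
    (flagged$all_flatness_above |
       (flagged$zero_crossings >= zc_band[1] & flagged$zero_crossings <= zc_band[2]))
  flagged[!(noisy & flagged$vehicle_like), names(preds)]
}

#' Flag candidate high-chaos segments
#'
#' A segment is a candidate when any of its (already filtered and pruned)
#' predictions maps to the high-chaos group, or — irrespective of its
#' predictions, including an empty table — when any of its frame RMSE
#' values exceeds 7x the participant's mean RMSE (the loudness override
#' for very loud segments the sound-event classifier missed). When both
#' fire, the recorded trigger is the high-group class.
#'
#' @param preds Pruned prediction tibble.
#' @param audio_summary Per-segment summary (needs `max_rmse`); may be
#'   `NULL` when only prediction-driven detection is wanted.
#' @param stats Participant stats from [participant_mean_rmse()]; may be
#'   `NULL` with `audio_summary = NULL`.
#' @param group_map Group map from [build_group_map()].
#' @param loudness_multiplier Loudness-override multiple (default 7).
#' @return Tibble: `participant_id`, `segment_index`, `is_candidate`,
#'   `trigger` (`"high_group_class"`, `"loudness_override"` or `"none"`).
#' @export
detect_high_chaos <- function(preds, audio_summary = NULL, stats = NULL,
                              group_map = build_group_map(default_class_metadata()),
                              loudness_multiplier = 7) {
  flagged <- join_group_flags(preds, group_map)
  by_pred <- flagged |>
    dplyr::group_by(.data$participant_id, .data$segment_index) |>
    dplyr::summarise(pred_high = any(.data$chaos_group %in% "high"),
                     .groups = "drop")
  universe <- by_pred[c("participant_id", "segment_index")]
  if (!is.null(audio_summary)) {
    assert_columns(audio_summary, c("participant_id", "segment_index", "max_rmse"),
                   "audio summary")
    universe <- dplyr::distinct(dplyr::bind_rows(
      universe, audio_summary[c("participant_id", "segment_index")]
    ))
  }
  out <- universe |>
    dplyr::left_join(by_pred, by = c("participant_id", "segment_index")) |>
    dplyr::mutate(pred_high = !is.na(.data$pred_high) & .data$pred_high)
  if (!is.null(audio_summary) && !is.null(stats)) {
    assert_columns(stats, c("participant_id", "mean_rmse"), "participant stats")
    out <- out |>
      dplyr::left_join(audio_summary[c("participant_id", "segment_index", "max_rmse")],
                       by = c("participant_id", "segment_index")) |>
      dplyr::left_join(stats[c("participant_id", "mean_rmse")],
                       by = "participant_id") |>
      dplyr::mutate(loud = !is.na(.data$max_rmse) & !is.na(.data$mean_rmse) &
                      .data$max_rmse > loudness_multiplier * .data$mean_rmse)
  } else {
    out$loud <- FALSE
  }
  out |>
    dplyr::mutate(
      is_candidate = .data$pred_high | .data$loud,
      trigger = dplyr::case_when(
        .data$pred_high ~ "high_group_class",
        .data$loud ~ "loudness_override",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select("participant_id", "segment_index", "is_candidate", "trigger") |>
    dplyr::arrange(.data$participant_id, .data$segment_index)
}

#' Run the full high-chaos detector pipeline
#'
#' Convenience wrapper chaining the pipeline on raw inputs: top-10 /
#' confidence-floor filtering, cry/babble pruning, white-noise/vehicle
#' pruning, then candidate selection with the loudness override.
#'
#' @param segments Segment tibble with waveforms (`samples`), or `NULL`
#'   to run on predictions alone (no pruning, no loudness override).
#' @param preds Raw prediction tibble.
#' @param class_metadata Class metadata (default shipped table).
#' @param quality_threshold,k,min_confidence,loudness_multiplier Tuning
#'   knobs; defaults are the deployed ones.
#' @return Candidate tibble as from [detect_high_chaos()].
#' @export
run_detector <- function(segments, preds,
                         class_metadata = default_class_metadata(),
                         quality_threshold = 0.33, k = 10,
                         min_confidence = 1e-4, loudness_multiplier = 7) {
  group_map <- build_group_map(class_metadata, quality_threshold)
  preds <- filter_topk_confidence(preds, k = k, min_confidence = min_confidence)
  if (is.null(segments)) {
    return(detect_high_chaos(preds, group_map = group_map,
                             loudness_multiplier = loudness_multiplier))
  }
  summary <- segment_audio_summary(segments)
  stats <- participant_mean_rmse(segments)
  preds <- prune_cry_babble(preds, summary, stats, group_map)
  preds <- prune_whitenoise_vehicle(preds, summary, group_map)
  detect_high_chaos(preds, summary, stats, group_map,
                    loudness_multiplier = loudness_multiplier)
}

#' Matched random comparison sample
#'
#' For each participant, samples (without replacement) as many segments
#' as the detector flagged for that participant — the size-matched random
#' baseline the enrichment factor compares against.
#'
#' @param labels Ground-truth tibble (`participant_id`, `segment_index`,
#'   `chaos_level`).
#' @param results Detector results from [detect_high_chaos()].
#' @param seed Integer seed.
#' @return Subset of `labels`.
#' @export
sample_matched_random <- function(labels, results, seed = 1L) {
  assert_columns(labels, c("participant_id", "segment_index", "chaos_level"),
                 "label table")
  counts <- results |>
    dplyr::filter(.data$is_candidate) |>
    dplyr::count(.data$participant_id)
  with_seed(seed, {
    picks <- lapply(seq_len(nrow(counts)), function(i) {
      pool <- labels[labels$participant_id == counts$participant_id[i], ]
      pool[sample.int(nrow(pool), min(counts$n[i], nrow(pool))), ]
    })
    dplyr::bind_rows(picks)
  })
}

#' Detector efficiency report
#'
#' Scores the detector against ground truth: recall and precision for the
#' high-chaos class (level 3), the fraction of all segments flagged, and
#' the enrichment factor — the high-chaos rate among candidates divided
#' by the high-chaos rate in a size-matched random sample.
#'
#' @param results Detector results from [detect_high_chaos()].
#' @param labels Ground-truth tibble (`participant_id`, `segment_index`,
#'   `chaos_level`).
#' @param random_sample Matched random sample of `labels` rows (see
#'   [sample_matched_random()]); `NULL` skips the enrichment factor.
#' @return One-row tibble of class `detector_report`: `recall`,
#'   `precision`, `candidate_fraction`, `candidate_high_rate`,
#'   `random_high_rate`, `enrichment`, `n_candidates`, `n_segments`.
#' @export
evaluate_detector <- function(results, labels, random_sample = NULL) {
  assert_columns(labels, c("participant_id", "segment_index", "chaos_level"),
                 "label table")
  joined <- dplyr::inner_join(
    results, labels, by = c("participant_id", "segment_index")
  )
  n_pos <- sum(joined$chaos_level == 3L)
  n_cand <- sum(joined$is_candidate)
  tp <- sum(joined$is_candidate & joined$chaos_level == 3L)
  precision <- if (n_cand == 0) NA_real_ else tp / n_cand
  if (n_cand == 0) warning("Empty candidate set: precision undefined.")
  cand_rate <- precision
  rand_rate <- if (is.null(random_sample)) NA_real_ else {
    mean(random_sample$chaos_level == 3L)
  }
  enrichment <- if (is.na(rand_rate) || is.na(cand_rate)) NA_real_ else {
    if (rand_rate == 0) Inf else cand_rate / rand_rate
  }
  structure(
    tibble::tibble(
      recall = if (n_pos == 0) NA_real_ else tp / n_pos,
      precision = precision,
      candidate_fraction = n_cand / nrow(joined),
      candidate_high_rate = cand_rate,
      random_high_rate = rand_rate,
      enrichment = enrichment,
      n_candidates = n_cand,
      n_segments = nrow(joined)
    ),
    class = c("detector_report", "tbl_df", "tbl", "data.frame")
  )
}
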