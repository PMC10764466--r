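mini_meta <- function() {
  tibble::tibble(
    class_name = c("Children shouting", "White noise", "Vehicle",
                   "Baby cry, infant cry", "Babbling", "Speech", "Mumble"),
    quality_estimate = c(0.8, 0.66, 0.65, 0.8, 0.47, 0.88, 0.30),
    excluded = FALSE,
    chaos_group = c("high", "non_high", "high", "high", "non_high",
                    "non_high", "non_high"),
    vehicle_like = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    cry_like = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    babble_like = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}

pred_row <- function(class_name, confidence, index = 0L, pid = "p1") {
  tibble::tibble(participant_id = pid, segment_index = as.integer(index),
                 class_name = class_name, confidence = confidence)
}

summary_row <- function(index = 0L, max_rmse = 0.1, flat = FALSE, zc = 200L,
                        pid = "p1") {
  tibble::tibble(participant_id = pid, segment_index = as.integer(index),
                 max_rmse = max_rmse, all_flatness_above = flat,
                 zero_crossings = as.integer(zc), peak_amplitude = max_rmse)
}

stats_row <- function(mean_rmse = 0.05, pid = "p1") {
  tibble::tibble(participant_id = pid, mean_rmse = mean_rmse)
}

test_that("group map drops low-quality and excluded classes and keeps the rest", {
  gm <- build_group_map(mini_meta())
  expect_false("Mumble" %in% gm$class_name) # quality 0.30 <= 0.33
  expect_true("Children shouting" %in% gm$class_name)
  expect_identical(gm$chaos_group[gm$class_name == "Children shouting"], "high")

  meta <- mini_meta()
  meta$quality_estimate[meta$class_name == "Speech"] <- 0.33 # boundary: dropped
  expect_false("Speech" %in% build_group_map(meta)$class_name)

  meta$excluded[meta$class_name == "Vehicle"] <- TRUE
  expect_false("Vehicle" %in% build_group_map(meta)$class_name)

  expect_equal(nrow(build_group_map(mini_meta()[0, ])), 0L)

  bad <- mini_meta()
  bad$chaos_group[2] <- NA
  expect_error(build_group_map(bad), "White noise")
})

test_that("top-k/confidence-floor filtering keeps at most 10 predictions above 1e-4", {
  set.seed(31)
  p15 <- pred_row(paste0("c", 1:15), runif(15, 0.01, 0.9))
  kept <- filter_topk_confidence(p15)
  expect_equal(nrow(kept), 10L)
  expect_equal(sort(kept$confidence, decreasing = TRUE),
               sort(p15$confidence, decreasing = TRUE)[1:10])

  low <- pred_row(c("a", "b"), c(5e-5, 1e-4))
  kept <- filter_topk_confidence(low)
  expect_identical(kept$class_name, "b") # 5e-5 below the 0.01% floor; 1e-4 kept

  expect_equal(nrow(filter_topk_confidence(pred_row(character(0), numeric(0)))), 0L)
})

test_that("cry/babble pruning keeps the class consistent with segment loudness", {
  gm <- build_group_map(mini_meta())
  both <- pred_row(c("Baby cry, infant cry", "Babbling", "Speech"),
                   c(0.6, 0.4, 0.2))
  loud <- prune_cry_babble(both, summary_row(max_rmse = 0.2),
                           stats_row(mean_rmse = 0.05), gm) # 4x mean: loud
  expect_true("Baby cry, infant cry" %in% loud$class_name)
  expect_false("Babbling" %in% loud$class_name)
  expect_true("Speech" %in% loud$class_name)

  quiet <- prune_cry_babble(both, summary_row(max_rmse = 0.1),
                            stats_row(mean_rmse = 0.05), gm) # 2x mean: quiet
  expect_false("Baby cry, infant cry" %in% quiet$class_name)
  expect_true("Babbling" %in% quiet$class_name)

  only_cry <- pred_row("Baby cry, infant cry", 0.6)
  expect_identical(prune_cry_babble(only_cry, summary_row(), stats_row(), gm),
                   only_cry)

  expect_error(prune_cry_babble(both, NULL, NULL, gm), "stats")
})

test_that("vehicle predictions are dropped on white-noise-like segments only", {
  gm <- build_group_map(mini_meta())
  preds <- pred_row(c("Vehicle", "Speech"), c(0.5, 0.3))

  flat_seg <- prune_whitenoise_vehicle(preds, summary_row(flat = TRUE), gm)
  expect_false("Vehicle" %in% flat_seg$class_name)
  expect_true("Speech" %in% flat_seg$class_name) # only vehicle-like removed

  zc_seg <- prune_whitenoise_vehicle(preds, summary_row(zc = 1500L), gm)
  expect_false("Vehicle" %in% zc_seg$class_name)
  expect_identical(prune_whitenoise_vehicle(preds, summary_row(zc = 1000L), gm)$class_name,
                   "Speech") # band is inclusive
  tone_seg <- prune_whitenoise_vehicle(preds, summary_row(flat = FALSE, zc = 200L), gm)
  expect_true("Vehicle" %in% tone_seg$class_name)
})

test_that("pruning conditions hold on constructed waveforms", {
  gm <- build_group_map(mini_meta())
  set.seed(32)
  wn <- as_segment(rnorm(110250) * 0.1, index = 0L)
  tone <- as_segment(make_sine(440, 0.3), index = 1L)
  sm <- segment_audio_summary(dplyr::bind_rows(wn, tone))
  expect_true(sm$all_flatness_above[1]) # white noise
  expect_false(sm$all_flatness_above[2]) # pure tone
  preds <- dplyr::bind_rows(pred_row("Vehicle", 0.5, index = 0L),
                            pred_row("Vehicle", 0.5, index = 1L))
  out <- prune_whitenoise_vehicle(preds, sm, gm)
  kept_idx <- out$segment_index
  expect_false(0L %in% kept_idx) # dropped on the noise segment
  expect_true(1L %in% kept_idx || sm$zero_crossings[2] >= 1000) # kept on the tone
})

test_that("candidates are triggered by high-group classes or the 7x loudness override", {
  gm <- build_group_map(mini_meta())

  scream <- detect_high_chaos(pred_row("Children shouting", 0.7),
                              summary_row(max_rmse = 0.1), stats_row(), gm)
  expect_true(scream$is_candidate)
  expect_identical(scream$trigger, "high_group_class")

  loud <- detect_high_chaos(pred_row("Speech", 0.5),
                            summary_row(max_rmse = 0.41), # 8.2x mean of 0.05
                            stats_row(), gm)
  expect_true(loud$is_candidate)
  expect_identical(loud$trigger, "loudness_override")

  quiet <- detect_high_chaos(pred_row("White noise", 0.6),
                             summary_row(max_rmse = 0.1), stats_row(), gm)
  expect_false(quiet$is_candidate)
  expect_identical(quiet$trigger, "none")

  at7x <- detect_high_chaos(pred_row("Speech", 0.5),
                            summary_row(max_rmse = 0.35), stats_row(), gm)
  expect_false(at7x$is_candidate) # strictly greater than 7x required
})

test_that("the loudness override fires even with an empty prediction table", {
  gm <- build_group_map(mini_meta())
  empty <- pred_row(character(0), numeric(0))
  res <- detect_high_chaos(empty, summary_row(max_rmse = 0.5), stats_row(), gm)
  expect_true(res$is_candidate)
  expect_identical(res$trigger, "loudness_override")
})

test_that("adding a high-group prediction never un-flags a candidate", {
  gm <- build_group_map(mini_meta())
  set.seed(33)
  pool <- c("Speech", "White noise", "Babbling", "Children shouting", "Vehicle")
  for (i in 1:20) {
    cls <- sample(pool, sample(1:4, 1))
    preds <- pred_row(cls, runif(length(cls), 0.01, 0.9))
    sm <- summary_row(max_rmse = runif(1, 0.01, 0.6))
    before <- detect_high_chaos(preds, sm, stats_row(), gm)
    more <- dplyr::bind_rows(preds, pred_row("Children shouting", 0.8))
    after <- detect_high_chaos(more, sm, stats_row(), gm)
    expect_true(!before$is_candidate || after$is_candidate)
  }
})

test_that("pruning and filtering never increase the prediction count", {
  gm <- build_group_map(mini_meta())
  set.seed(34)
  for (i in 1:15) {
    cls <- sample(mini_meta()$class_name, sample(2:7, 1), replace = TRUE)
    preds <- pred_row(cls, runif(length(cls), 1e-6, 1))
    f <- filter_topk_confidence(preds)
    expect_lte(nrow(f), min(nrow(preds), 10))
    sm <- summary_row(max_rmse = runif(1, 0.01, 0.4),
                      flat = runif(1) < 0.5,
                      zc = sample(c(200L, 2000L), 1))
    p1 <- prune_cry_babble(f, sm, stats_row(), gm)
    expect_lte(nrow(p1), nrow(f))
    p2 <- prune_whitenoise_vehicle(p1, sm, gm)
    expect_lte(nrow(p2), nrow(p1))
  }
})

test_that("detector efficiency reproduces the printed enrichment arithmetic", {
  ## candidates with a 16.8% true high-chaos rate vs a random sample at
  ## 2.02% give an 8.32-fold enrichment
  res <- tibble::tibble(participant_id = "p1", segment_index = 0:999,
                        is_candidate = TRUE, trigger = "high_group_class")
  labels <- tibble::tibble(participant_id = "p1", segment_index = 0:999,
                           chaos_level = c(rep(3L, 168), rep(1L, 832)))
  rand <- tibble::tibble(participant_id = "p1", segment_index = 0:9999,
                         chaos_level = c(rep(3L, 202), rep(0L, 9798)))
  rep <- evaluate_detector(res, labels, rand)
  expect_equal(rep$candidate_high_rate, 0.168)
  expect_equal(rep$random_high_rate, 0.0202)
  expect_lt(abs(rep$enrichment - 8.32), 0.005)
})

test_that("enrichment is 1 when candidates and the random sample coincide", {
  labels <- label_table(500, seed = 35)
  res <- tibble::tibble(participant_id = labels$participant_id,
                        segment_index = labels$segment_index,
                        is_candidate = TRUE, trigger = "high_group_class")
  rep <- evaluate_detector(res, labels, labels)
  expect_equal(rep$enrichment, 1)
})

test_that("an empty candidate set yields undefined precision with a warning", {
  labels <- label_table(100, seed = 36)
  res <- tibble::tibble(participant_id = labels$participant_id,
                        segment_index = labels$segment_index,
                        is_candidate = FALSE, trigger = "none")
  expect_warning(rep <- evaluate_detector(res, labels), "precision undefined")
  expect_true(is.na(rep$precision))
})

test_that("matched random samples are size-matched per participant", {
  labels <- dplyr::bind_rows(label_table(200, pid = "a", seed = 37),
                             label_table(300, pid = "b", seed = 38))
  res <- labels |>
    dplyr::mutate(is_candidate = segment_index < ifelse(participant_id == "a", 20, 50),
                  trigger = ifelse(is_candidate, "high_group_class", "none"))
  rand <- sample_matched_random(labels, res, seed = 39)
  expect_equal(sum(rand$participant_id == "a"), 20L)
  expect_equal(sum(rand$participant_id == "b"), 50L)
  expect_false(any(duplicated(segment_key(rand$participant_id, rand$segment_index))))
})
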