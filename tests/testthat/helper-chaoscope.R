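## Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

## a pure sine segment at the canonical rate
make_sine <- function(freq, amp = 0.5, seconds = 5) {
  t <- (seq_len(seconds * 22050) - 1) / 22050
  amp * sin(2 * pi * freq * t)
}

## one-row segment tibble around a waveform
as_segment <- function(samples, pid = "p1", index = 0L) {
  tibble::tibble(participant_id = pid, segment_index = as.integer(index),
                 start_time_s = index * 5, samples = list(samples))
}

## labels-only recording (no audio), enough for prediction-table and
## balanced-sampling machinery
label_table <- function(n, prevalence = c(0.25, 0.25, 0.25, 0.25),
                        pid = "p1", seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    participant_id = pid,
    segment_index = seq_len(n) - 1L,
    chaos_level = sample(0:3, n, replace = TRUE, prob = prevalence)
  )
}

## small labeled multi-participant soundscape datasets, prepared for the
## model pipeline; built once and reused across test files
easy_dataset <- function() {
  memo("easy", function() {
    rec <- dplyr::bind_rows(lapply(1:3, function(i) {
      generate_recording(sprintf("easy%02d", i), hours = 0.1,
                         seed = 7000 + i, confounded = FALSE)
    }))
    prepare_chaos_data(rec)
  })
}

confounded_dataset <- function() {
  memo("confounded", function() {
    rec <- dplyr::bind_rows(lapply(1:3, function(i) {
      generate_recording(sprintf("conf%02d", i), hours = 0.1,
                         seed = 8000 + i, confounded = TRUE)
    }))
    prepare_chaos_data(rec)
  })
}

## a fast fake model for evaluation-harness tests: records its training
## set and predicts the majority training class
majority_factory <- function(log_env = NULL) {
  function(train_data, seed = 1L) {
    if (!is.null(log_env)) {
      log_env$train_participants <- c(log_env$train_participants,
                                      list(unique(train_data$participant_id)))
    }
    lvl <- as.integer(names(which.max(table(train_data$chaos_level))))
    structure(list(level = lvl), class = "majority_model")
  }
}

predict.majority_model <- function(object, newdata, ...) {
  tibble::tibble(participant_id = newdata$participant_id,
                 segment_index = newdata$segment_index,
                 predicted_level = object$level)
}
registerS3method("predict", "majority_model", predict.majority_model)
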