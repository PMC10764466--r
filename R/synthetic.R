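#' Scene specification for one synthetic 5-s soundscape
#'
#' Describes a single labeled synthetic segment: its chaos level (0-3),
#' duration, number of overlapping sources, source kinds, amplitude range
#' and seed. Defaults encode the study conditions: level 0 is silence
#' (no sources, peak below the 0.01 silence threshold), level 1 soft
#' familiar sounds, level 2 moderately stimulating mixtures, level 3 a
#' dense cacophony (>= 3 overlapping sources with impulses). In
#' `confounded` mode the amplitude ranges of levels 1-3 coincide and level
#' 1 becomes a loud steady white-noise source (a white-noise machine)
#' while level 3 is a quiet dense cacophony, so volume alone cannot
#' separate the classes.
#'
#' @param chaos_level Integer 0-3.
#' @param seed Integer seed; all of the scene's randomness flows from it.
#' @param duration_s Scene duration in seconds (default 5).
#' @param n_sources Number of overlapping sources; defaults by level.
#' @param amplitude_range Length-2 numeric in `[0, 1]`; target peak range.
#' @param source_kinds Subset of `tone`, `harmonic_stack`, `am_speechlike`,
#'   `white_noise`, `impulse`; defaults by level and mode.
#' @param confounded Use the volume-confounded recipe (default `FALSE`).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(chaos_level, seed, duration_s = 5, n_sources = NULL,
                       amplitude_range = NULL, source_kinds = NULL,
                       confounded = FALSE) {
  if (!chaos_level %in% CHAOS_LEVELS) abort("`chaos_level` must be one of 0, 1, 2, 3.")
  assert_scalar_number(duration_s, "duration_s", lower = 1e-9)
  level <- as.integer(chaos_level)

  if (is.null(n_sources)) {
    n_sources <- switch(as.character(level), "0" = 0L, "1" = 2L, "2" = 3L, "3" = 5L)
    if (confounded && level == 1L) n_sources <- 1L
  }
  n_sources <- as.integer(n_sources)
  if (level == 0L && n_sources > 0L) {
    abort("Level 0 (silence) cannot have sources: set n_sources = 0.")
  }
  if (level > 0L && n_sources < 1L) abort("Levels 1-3 need at least one source.")

  if (is.null(source_kinds)) {
    source_kinds <- if (level == 0L) {
      character(0)
    } else if (confounded) {
      switch(as.character(level),
             "1" = "white_noise",
             "2" = c("tone", "harmonic_stack", "am_speechlike"),
             "3" = c("tone", "harmonic_stack", "am_speechlike", "impulse"))
    } else {
      switch(as.character(level),
             "1" = c("tone", "harmonic_stack"),
             "2" = c("am_speechlike", "harmonic_stack", "tone"),
             "3" = c("tone", "harmonic_stack", "am_speechlike", "white_noise", "impulse"))
    }
  }
  known <- c("tone", "harmonic_stack", "am_speechlike", "white_noise", "impulse")
  if (!all(source_kinds %in% known)) {
    abort(sprintf("Unknown source kind(s): %s.",
                  paste(setdiff(source_kinds, known), collapse = ", ")))
  }
  if (level == 3L && n_sources < 3L && !"impulse" %in% source_kinds) {
    abort("Level 3 requires >= 3 sources or an impulse source.")
  }

  if (is.null(amplitude_range)) {
    amplitude_range <- if (confounded && level >= 1L) {
      c(0.15, 0.9)
    } else {
      switch(as.character(level),
             "0" = c(0, 0.002), "1" = c(0.05, 0.2),
             "2" = c(0.25, 0.5), "3" = c(0.6, 1.0))
    }
  }
  if (length(amplitude_range) != 2 || any(amplitude_range < 0) ||
      any(amplitude_range > 1) || amplitude_range[1] > amplitude_range[2]) {
    abort("`amplitude_range` must be an increasing pair within [0, 1].")
  }

  structure(
    list(chaos_level = level, duration_s = duration_s, n_sources = n_sources,
         amplitude_range = amplitude_range, source_kinds = source_kinds,
         confounded = isTRUE(confounded), seed = as.integer(seed)),
    class = "scene_spec"
  )
}

## --- source recipes ------------------------------------------------------
## tones 200-2,000 Hz; harmonic stacks 3-6 partials; "speechlike" =
## band-limited noise with 3-8 Hz amplitude modulation; impulse = an
## exponentially decaying broadband click; white noise = Gaussian.

synth_tone <- function(t, freq_range = c(200, 2000)) {
  sin(2 * pi * runif(1, freq_range[1], freq_range[2]) * t + runif(1, 0, 2 * pi))
}

synth_harmonic_stack <- function(t, f0_range = c(150, 500)) {
  f0 <- runif(1, f0_range[1], f0_range[2])
  k <- sample(3:6, 1)
  rowSums(vapply(seq_len(k), function(j) {
    sin(2 * pi * j * f0 * t + runif(1, 0, 2 * pi)) / j
  }, numeric(length(t))))
}

synth_band_noise <- function(n, sr, lo, hi) {
  x <- rnorm(n)
  spec <- fft(x)
  freqs <- (seq_len(n) - 1) * sr / n
  freqs <- pmin(freqs, sr - freqs) # mirrored axis
  spec[freqs < lo | freqs > hi] <- 0
  Re(fft(spec, inverse = TRUE)) / n
}

synth_am_speechlike <- function(t, sr) {
  carrier <- synth_band_noise(length(t), sr, runif(1, 900, 1400), runif(1, 2600, 3600))
  env <- 0.5 + 0.5 * sin(2 * pi * runif(1, 3, 8) * t + runif(1, 0, 2 * pi))
  carrier * env
}

synth_white_noise <- function(n) rnorm(n)

synth_impulse <- function(t, sr) {
  n <- length(t)
  onset <- sample.int(max(1L, n - sr %/% 10), 1)
  tau <- runif(1, 0.005, 0.03)
  out <- numeric(n)
  tail_idx <- onset:n
  out[tail_idx] <- rnorm(length(tail_idx)) * exp(-(t[tail_idx] - t[onset]) / tau)
  out
}

## level-specific palettes keep the class signatures distinct: low-chaos
## tonal sources sit in a low register, higher levels spread upward
synth_source <- function(kind, t, sr, level = 2L) {
  x <- switch(kind,
              tone = synth_tone(t, if (level <= 1L) c(200, 700) else c(400, 2000)),
              harmonic_stack = synth_harmonic_stack(
                t, if (level <= 1L) c(120, 300) else c(250, 600)),
              am_speechlike = synth_am_speechlike(t, sr),
              white_noise = synth_white_noise(length(t)),
              impulse = synth_impulse(t, sr))
  peak <- max(abs(x))
  if (peak > 0) x / peak else x
}

#' Generate one labeled synthetic scene
#'
#' Synthesises the waveform a [scene_spec()] describes. Level-0 scenes are
#' near-silent (peak below 0.01 full scale); level-3 scenes mix at least
#' three overlapping sources or contain an impulse. Identical specs
#' (including seed) produce bit-identical waveforms.
#'
#' @param spec A [scene_spec()].
#' @return List with `samples` (mono, 22,050 Hz), `chaos_level`, and
#'   `meta` (source kinds drawn, target peak).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  sr <- CANONICAL_SR
  n <- as.integer(round(spec$duration_s * sr))
  t <- (seq_len(n) - 1) / sr
  with_seed(spec$seed, {
    if (spec$chaos_level == 0L) {
      amp <- runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
      return(list(samples = runif(n, -1, 1) * amp, chaos_level = 0L,
                  meta = list(kinds = character(0), n_sources = 0L, peak = amp)))
    }
    kinds <- sample(spec$source_kinds, spec$n_sources, replace = TRUE)
    ## anchor each level's signature: a level-2 scene carries its
    ## modulated band noise, a level-3 cacophony its impulse (and, in the
    ## separable condition, a broadband noise bed) whenever available
    force_kind <- function(kinds, kind, slot) {
      if (kind %in% spec$source_kinds && !kind %in% kinds && length(kinds) >= slot) {
        kinds[slot] <- kind
      }
      kinds
    }
    if (spec$chaos_level == 2L) kinds <- force_kind(kinds, "am_speechlike", 1L)
    if (spec$chaos_level == 3L) {
      kinds <- force_kind(kinds, "impulse", 1L)
      kinds <- force_kind(kinds, "white_noise", 2L)
    }
    mix <- rowSums(vapply(kinds, function(k) {
      synth_source(k, t, sr, level = spec$chaos_level) * runif(1, 0.5, 1)
    }, numeric(n)))
    ## confounded mode: a slow random loudness envelope plus RMS-matched
    ## gain decorrelates energy statistics from the chaos level
    if (spec$confounded) {
      depth <- runif(1, 0, 0.9)
      env <- 1 - depth * (0.5 + 0.5 * sin(2 * pi * runif(1, 0.2, 1.5) * t + runif(1, 0, 2 * pi)))
      mix <- mix * env
      target_rms <- runif(1, 0.25, 0.8) * spec$amplitude_range[2] / 3.5
      rms <- sqrt(mean(mix^2))
      if (rms > 0) mix <- mix * target_rms / rms
      peak <- max(abs(mix))
      if (peak > 1) mix <- mix / peak # guard against clipping
    } else {
      target <- runif(1, spec$amplitude_range[1], spec$amplitude_range[2])
      peak <- max(abs(mix))
      if (peak > 0) mix <- mix * target / peak
    }
    list(samples = mix, chaos_level = spec$chaos_level,
         meta = list(kinds = kinds, n_sources = spec$n_sources,
                     peak = max(abs(mix))))
  })
}

## per-level n_sources draw used by generate_recording
draw_n_sources <- function(level, confounded) {
  switch(as.character(level),
         "0" = 0L,
         "1" = if (confounded) 1L else sample(1:2, 1),
         "2" = sample(2:3, 1),
         "3" = sample(4:6, 1))
}

#' Generate a labeled synthetic recording
#'
#' Produces `round(hours * 720)` labeled 5-s segments (each hour of audio
#' holds 720 segments) with chaos levels drawn from `prevalence`. All
#' randomness flows from `seed`; the same call is bit-reproducible.
#'
#' @param participant_id Identifier string.
#' @param hours Recording length in hours (> 0).
#' @param prevalence Length-4 nonnegative vector summing to 1: fraction of
#'   segments at levels 0-3.
#' @param seed Integer seed.
#' @param confounded Use the volume-confounded recipe (default `FALSE`).
#' @return Segment tibble: `participant_id`, `segment_index`,
#'   `start_time_s`, `samples` (list-column), `chaos_level`, `n_sources`.
#' @export
generate_recording <- function(participant_id, hours,
                               prevalence = c(0.25, 0.25, 0.25, 0.25),
                               seed = 1L, confounded = FALSE) {
  assert_scalar_number(hours, "hours", lower = 1e-9)
  if (length(prevalence) != 4 || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-8) {
    abort("`prevalence` must be 4 nonnegative fractions summing to 1.")
  }
  n <- as.integer(round(hours * SEGMENTS_PER_HOUR))
  plan <- with_seed(seed, {
    labels <- sample(CHAOS_LEVELS, n, replace = TRUE, prob = prevalence)
    tibble::tibble(
      segment_index = seq_len(n) - 1L,
      chaos_level = as.integer(labels),
      n_sources = vapply(labels, draw_n_sources, integer(1), confounded = confounded),
      scene_seed = sample.int(2147483646L, n)
    )
  })
  samples <- lapply(seq_len(n), function(i) {
    spec <- scene_spec(plan$chaos_level[i], seed = plan$scene_seed[i],
                       n_sources = plan$n_sources[i], confounded = confounded)
    generate_scene(spec)$samples
  })
  tibble::tibble(
    participant_id = as.character(participant_id),
    segment_index = plan$segment_index,
    start_time_s = plan$segment_index * 5,
    samples = samples,
    chaos_level = plan$chaos_level,
    n_sources = plan$n_sources
  )
}

#' Noise model for synthetic sound-event prediction tables
#'
#' Emulates the error modes of an external 521-class sound-event
#' classifier: missed high-chaos detections, false high-chaos alarms, and
#' the two systematic confusions the pruning heuristics target
#' (infant cry vs. babble, white noise vs. vehicles).
#'
#' @param miss_rate P(a true level-3 segment carries no high-group class).
#' @param false_alarm_rate P(a level < 3 segment carries a high-group class).
#' @param cry_babble_rate P(a level-3 high class is emitted as cry + babble
#'   jointly); also P(a quiet segment gains a spurious babble + cry pair).
#' @param whitenoise_vehicle_rate P(a white-noise-like segment gains a
#'   spurious vehicle prediction).
#' @param seed Integer seed.
#' @return A `prediction_noise_spec` list.
#' @export
prediction_noise_spec <- function(miss_rate = 0.1, false_alarm_rate = 0.05,
                                  cry_babble_rate = 0, whitenoise_vehicle_rate = 0,
                                  seed = 1L) {
  assert_probability(miss_rate, "miss_rate")
  assert_probability(false_alarm_rate, "false_alarm_rate")
  assert_probability(cry_babble_rate, "cry_babble_rate")
  assert_probability(whitenoise_vehicle_rate, "whitenoise_vehicle_rate")
  structure(list(miss_rate = miss_rate, false_alarm_rate = false_alarm_rate,
                 cry_babble_rate = cry_babble_rate,
                 whitenoise_vehicle_rate = whitenoise_vehicle_rate,
                 seed = as.integer(seed)),
            class = "prediction_noise_spec")
}

## filler class pools; all names exist in default_class_metadata()
POOL_NEUTRAL <- c("Silence", "Wind", "White noise", "Shuffling cards",
                  "Microwave", "Walk, footsteps", "Chime", "Classical music")
POOL_MEDIUM <- c("Child speech, kid speaking", "Doorbell", "Alarm clock",
                 "Hair dryer", "Pop music", "Acoustic guitar",
                 "Sink (filling or washing)", "Toilet flush")
POOL_HIGH <- c("Children shouting", "Screaming", "Applause", "Drum roll",
               "Fire alarm", "Smash, crash")
CLASS_CRY <- "Baby cry, infant cry"
CLASS_BABBLE <- "Babbling"
CLASS_VEHICLE <- c("Vehicle", "Car")

#' Generate a synthetic sound-event prediction table
#'
#' For every segment of a labeled recording, emits 1-15 (class, confidence)
#' records with the structure an external everyday-sound classifier would
#' produce. True level-3 segments carry a high-group class with probability
#' `1 - miss_rate`; lower-level segments with probability
#' `false_alarm_rate`. The confusion channels optionally emit joint
#' cry/babble pairs and spurious vehicle labels on white-noise-like
#' segments.
#'
#' @param recording Segment tibble with `chaos_level` (from
#'   [generate_recording()]).
#' @param noise A [prediction_noise_spec()].
#' @return Tibble: `participant_id`, `segment_index`, `class_name`,
#'   `confidence`.
#' @export
generate_prediction_table <- function(recording, noise = prediction_noise_spec()) {
  assert_columns(recording, c("participant_id", "segment_index", "chaos_level"),
                 "recording")
  stopifnot(inherits(noise, "prediction_noise_spec"))
  with_seed(noise$seed, {
    rows <- lapply(seq_len(nrow(recording)), function(i) {
      level <- recording$chaos_level[i]
      pool <- if (level <= 1) POOL_NEUTRAL else c(POOL_NEUTRAL, POOL_MEDIUM)
      n_fill <- sample(1:6, 1)
      cls <- sample(pool, n_fill, replace = FALSE)
      conf <- runif(n_fill, 1e-4, 0.3)
      ## occasional sub-floor prediction, to be discarded by the
      ## confidence-floor filter downstream
      if (runif(1) < 0.3) {
        cls <- c(cls, sample(pool, 1))
        conf <- c(conf, runif(1, 1e-6, 9e-5))
      }
      emit_high <- if (level == 3L) runif(1) >= noise$miss_rate else
        runif(1) < noise$false_alarm_rate
      if (emit_high) {
        if (level == 3L && runif(1) < noise$cry_babble_rate) {
          cls <- c(cls, CLASS_CRY, CLASS_BABBLE)
          conf <- c(conf, runif(1, 0.3, 0.95), runif(1, 0.1, 0.5))
        } else {
          cls <- c(cls, sample(POOL_HIGH, 1))
          conf <- c(conf, runif(1, 0.3, 0.95))
        }
      }
      if (level < 3L && runif(1) < noise$whitenoise_vehicle_rate) {
        cls <- c(cls, sample(CLASS_VEHICLE, 1), "White noise")
        conf <- c(conf, runif(1, 0.3, 0.8), runif(1, 0.1, 0.5))
      }
      tibble::tibble(
        participant_id = recording$participant_id[i],
        segment_index = recording$segment_index[i],
        class_name = cls,
        confidence = conf
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Write a synthetic recording to disk
#'
#' Writes one 16-bit PCM WAV per recording plus a labels CSV
#' (`participant_id`, `segment_index`, `chaos_level`).
#'
#' @param recording Segment tibble from [generate_recording()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in unique(recording$participant_id)) {
    sub <- recording[recording$participant_id == pid, ]
    sub <- sub[order(sub$segment_index), ]
    write_wav(unlist(sub$samples), file.path(dir, paste0(pid, ".wav")))
  }
  labels <- recording[c("participant_id", "segment_index", "chaos_level")]
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write/read sound-event predictions as JSONL
#'
#' One JSON object per line: `{"participant_id", "segment_index",
#' "class_name", "confidence"}`.
#'
#' @param predictions Prediction tibble.
#' @param path File path.
#' @return `path` invisibly, or the prediction tibble for the reader.
#' @export
write_predictions_jsonl <- function(predictions, path) {
  lines <- vapply(seq_len(nrow(predictions)), function(i) {
    jsonlite::toJSON(as.list(predictions[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions_jsonl
#' @export
read_predictions_jsonl <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  })
  dplyr::bind_rows(rows)
}
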