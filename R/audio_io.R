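#' Load a recording and normalise it to the canonical audio contract
#'
#' Reads a WAV file of any rate/channel layout, mixes it down to mono
#' (channel mean) and resamples it to 22,050 Hz with a polyphase FIR
#' resampler, the contract every downstream operation assumes.
#'
#' @param path Path to a WAV file.
#' @param participant_id Identifier attached to every derived segment.
#' @return A `chaos_recording`: list with `participant_id`, `samples`
#'   (mono, `[-1, 1]`), `sample_rate` (22,050) and `duration_s`.
#' @export
load_recording <- function(path, participant_id) {
  wav <- read_wav(path)
  if (nrow(wav$samples) == 0) {
    abort(sprintf("Recording is empty (zero samples): %s", path))
  }
  mono <- rowMeans(wav$samples)
  if (wav$sample_rate != CANONICAL_SR) {
    g <- gcd(CANONICAL_SR, wav$sample_rate)
    mono <- as.numeric(signal::resample(mono, CANONICAL_SR / g, wav$sample_rate / g))
  }
  mono <- pmax(-1, pmin(1, mono))
  new_recording(participant_id, mono)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Construct a recording from an in-memory waveform
#'
#' @param participant_id Identifier string.
#' @param samples Mono numeric waveform in `[-1, 1]` at 22,050 Hz.
#' @param sample_rate Sampling rate; must equal the canonical 22,050 Hz.
#' @return A `chaos_recording` object.
#' @export
new_recording <- function(participant_id, samples, sample_rate = CANONICAL_SR) {
  if (sample_rate != CANONICAL_SR) {
    abort("Recordings must be at the canonical 22,050 Hz; use load_recording() to resample.")
  }
  if (length(samples) == 0) abort("Recording has zero samples.")
  if (!all(is.finite(samples))) abort("Recording contains non-finite samples.")
  structure(
    list(
      participant_id = as.character(participant_id),
      samples = as.numeric(samples),
      sample_rate = CANONICAL_SR,
      duration_s = length(samples) / CANONICAL_SR
    ),
    class = "chaos_recording"
  )
}

#' @export
print.chaos_recording <- function(x, ...) {
  cat(sprintf("<chaos_recording> participant %s: %.1f s at %d Hz\n",
              x$participant_id, x$duration_s, x$sample_rate))
  invisible(x)
}

#' Segment a recording into non-overlapping 5-second analysis units
#'
#' Splits the waveform into contiguous 5-s segments (110,250 samples each);
#' a trailing remainder shorter than 5 s is dropped, so a recording of
#' duration `d` seconds yields `floor(d / 5)` segments. Indices are 0-based
#' and times are half-open `[start, start + 5)`.
#'
#' @param recording A `chaos_recording`.
#' @return A tibble with one row per segment: `participant_id`,
#'   `segment_index`, `start_time_s` and a `samples` list-column.
#' @export
segment_recording <- function(recording) {
  stopifnot(inherits(recording, "chaos_recording"))
  n_seg <- floor(length(recording$samples) / SEGMENT_SAMPLES)
  if (n_seg == 0) {
    return(tibble::tibble(
      participant_id = character(), segment_index = integer(),
      start_time_s = numeric(), samples = list()
    ))
  }
  idx <- seq_len(n_seg) - 1L
  tibble::tibble(
    participant_id = recording$participant_id,
    segment_index = idx,
    start_time_s = idx * 5,
    samples = lapply(idx, function(i) {
      recording$samples[(i * SEGMENT_SAMPLES + 1L):((i + 1L) * SEGMENT_SAMPLES)]
    })
  )
}

#' Number of 5-s segments a recording of given duration yields
#'
#' @param duration_s Duration in seconds (or `hours` via the helper arg).
#' @param hours Optional duration in hours; overrides `duration_s`.
#' @return Integer segment count, `floor(duration_s / 5)`.
#' @export
segment_count <- function(duration_s = NULL, hours = NULL) {
  if (!is.null(hours)) duration_s <- hours * 3600
  assert_scalar_number(duration_s, "duration_s", lower = 0)
  as.integer(floor(duration_s / SEGMENT_SECONDS))
}

#' Write a segment manifest CSV
#'
#' @param segments Segment tibble from [segment_recording()].
#' @param path Output CSV path.
#' @param source_path Optional path of the source WAV recorded per row.
#' @return `path`, invisibly.
#' @export
write_segment_manifest <- function(segments, path, source_path = NA_character_) {
  assert_columns(segments, c("participant_id", "segment_index", "start_time_s"),
                 "segment table")
  manifest <- dplyr::select(segments, "participant_id", "segment_index", "start_time_s")
  manifest$source_path <- source_path
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
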