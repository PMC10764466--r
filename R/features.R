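#' Framing convention for sliding-window features
#'
#' The canonical convention is a 512-sample window with a 256-sample hop,
#' centered: the signal is zero-padded by half a window on both sides so a
#' 5-s segment (110,250 samples) yields exactly `1 + floor(110250/256) = 431`
#' frames. Non-centered framing would give 429 and is kept available for
#' comparison only.
#'
#' @param window_samples Analysis window length in samples.
#' @param hop_samples Hop between frame starts in samples.
#' @param centered Pad by `window/2` on each side (default `TRUE`).
#' @param sample_rate Sampling rate in Hz.
#' @return A `framing_config` list.
#' @export
framing_config <- function(window_samples = 512L, hop_samples = 256L,
                           centered = TRUE, sample_rate = 22050L) {
  stopifnot(hop_samples <= window_samples, window_samples > 0, hop_samples > 0)
  structure(list(window_samples = as.integer(window_samples),
                 hop_samples = as.integer(hop_samples),
                 centered = isTRUE(centered),
                 sample_rate = as.integer(sample_rate)),
            class = "framing_config")
}

#' Number of frames produced by a framing convention
#'
#' @param n_samples Signal length in samples.
#' @param framing A [framing_config()].
#' @return Frame count: `1 + floor(n/hop)` when centered,
#'   `1 + floor((n - window)/hop)` otherwise (0 if the signal is shorter
#'   than one window).
#' @export
n_frames <- function(n_samples, framing = framing_config()) {
  if (framing$centered) {
    1L + as.integer(floor(n_samples / framing$hop_samples))
  } else {
    if (n_samples < framing$window_samples) return(0L)
    1L + as.integer(floor((n_samples - framing$window_samples) / framing$hop_samples))
  }
}

## window x n_frames matrix of raw (unwindowed) frames
frame_signal <- function(x, framing = framing_config()) {
  w <- framing$window_samples
  h <- framing$hop_samples
  nf <- n_frames(length(x), framing)
  if (nf == 0L) return(matrix(numeric(0), nrow = w, ncol = 0))
  if (framing$centered) {
    pad_left <- w %/% 2
    needed <- (nf - 1L) * h + w
    pad_right <- max(0L, needed - pad_left - length(x))
    x <- c(numeric(pad_left), x, numeric(pad_right))
  }
  starts <- (seq_len(nf) - 1L) * h
  idx <- outer(seq_len(w), starts, `+`)
  matrix(x[idx], nrow = w)
}

## periodic Hann window (standard for STFT analysis)
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

## magnitude spectrogram: (n_fft/2 + 1) x n_frames
stft_magnitude <- function(x, framing = framing_config(), n_fft = framing$window_samples) {
  frames <- frame_signal(x, framing)
  if (ncol(frames) == 0) return(matrix(numeric(0), nrow = n_fft %/% 2 + 1, ncol = 0))
  frames <- frames * hann_window(framing$window_samples)
  if (n_fft > framing$window_samples) {
    frames <- rbind(frames, matrix(0, n_fft - framing$window_samples, ncol(frames)))
  }
  spec <- stats::mvfft(frames)
  Mod(spec[seq_len(n_fft %/% 2 + 1), , drop = FALSE])
}

#' Framewise root-mean-square energy
#'
#' @param samples Mono waveform at 22,050 Hz.
#' @param framing A [framing_config()].
#' @return Numeric vector, one RMSE value per frame (431 for a 5-s segment
#'   under the default framing).
#' @export
frame_rmse <- function(samples, framing = framing_config()) {
  frames <- frame_signal(samples, framing)
  sqrt(colMeans(frames^2))
}

#' Peak amplitude of a segment
#'
#' @param samples Mono waveform.
#' @return `max(abs(samples))`.
#' @export
peak_amplitude <- function(samples) max(abs(samples))

#' Framewise spectral flatness
#'
#' Ratio of the geometric to the arithmetic mean of the power spectrum,
#' in `[0, 1]`: near 1 for white noise, near 0 for tonal sounds. Spectral
#' bins are floored at `amin` before the ratio, matching common practice.
#'
#' @param samples Mono waveform.
#' @param framing A [framing_config()].
#' @param amin Power floor (default `1e-10`).
#' @return Numeric vector, one flatness value per frame.
#' @export
spectral_flatness_series <- function(samples, framing = framing_config(), amin = 1e-10) {
  power <- pmax(stft_magnitude(samples, framing)^2, amin)
  exp(colMeans(log(power))) / colMeans(power)
}

#' Segment-level zero-crossing count
#'
#' Counts the number of times the signal crosses zero over the full
#' segment: transitions positive-to-negative or negative-to-positive,
#' passing through exact zeros counts as a single crossing.
#'
#' @param samples Mono waveform.
#' @return Integer crossing count.
#' @export
zero_crossings <- function(samples) {
  s <- sign(samples)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

## framewise zero-crossing rate: fraction of adjacent sample pairs in the
## frame with a strict sign change
frame_zcr <- function(samples, framing = framing_config()) {
  frames <- frame_signal(samples, framing)
  if (ncol(frames) == 0) return(numeric(0))
  crossings <- frames[-nrow(frames), , drop = FALSE] * frames[-1, , drop = FALSE] < 0
  colMeans(crossings)
}

## spectral centroid / bandwidth / rolloff from a magnitude spectrogram
spectral_shape <- function(mag, sample_rate, n_fft, rolloff_percent = 0.85) {
  freqs <- (seq_len(nrow(mag)) - 1) * sample_rate / n_fft
  total <- colSums(mag)
  safe <- pmax(total, 1e-12)
  centroid <- colSums(freqs * mag) / safe
  dev <- sweep(matrix(freqs, nrow(mag), ncol(mag)), 2, centroid, `-`)
  bandwidth <- sqrt(colSums(mag * dev^2) / safe)
  cs <- apply(mag, 2, cumsum)
  ge <- cs >= matrix(rolloff_percent * total, nrow(mag), ncol(mag), byrow = TRUE)
  rolloff <- freqs[nrow(mag) - colSums(ge) + 1L]
  list(centroid = centroid, bandwidth = bandwidth, rolloff = rolloff)
}

## triangular mel filterbank (HTK mel scale), n_mels x (n_fft/2 + 1)
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0, fmax = sample_rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (seq_len(n_fft %/% 2 + 1) - 1) * sample_rate / n_fft
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freqs - lo) / max(ctr - lo, 1e-9)
    down <- (hi - bin_freqs) / max(hi - ctr, 1e-9)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

## orthonormal DCT-II matrix (n_out x n_in), for MFCC computation
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  m <- cos(pi / n_in * outer(k, n + 0.5))
  m <- m * sqrt(2 / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

## framewise MFCCs: n_mfcc x n_frames from a magnitude spectrogram
frame_mfcc <- function(mag, sample_rate, n_fft, n_mfcc = 20, n_mels = 40) {
  fb <- mel_filterbank(n_mels, n_fft, sample_rate)
  mel_power <- fb %*% (mag^2)
  log_mel <- 10 * log10(pmax(mel_power, 1e-10))
  (dct_matrix(n_mfcc, n_mels) %*% log_mel)
}

feature53_names <- function() {
  base <- c(paste0("mfcc_", 1:20), "zcr", "flatness", "rolloff",
            "centroid", "bandwidth", "rmse")
  c(paste0("mean_", base), paste0("sd_", base), "peak_amplitude")
}

## population standard deviation (denominator n), used for all framewise stds
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract the 53-dimensional acoustic feature vector
#'
#' Framewise features (20 MFCCs, zero-crossing rate, spectral flatness,
#' rolloff, centroid, bandwidth, RMSE; window 512, 50% overlap, centered)
#' are summarised by their mean and standard deviation across frames
#' (26 x 2 = 52), and the segment peak amplitude is appended, giving 53
#' values. Column order is fixed: `mean_mfcc_1..20, mean_zcr,
#' mean_flatness, mean_rolloff, mean_centroid, mean_bandwidth, mean_rmse`,
#' the same 26 as `sd_*`, then `peak_amplitude`.
#'
#' @param samples Mono waveform at 22,050 Hz.
#' @param framing A [framing_config()].
#' @return Named numeric vector of length 53.
#' @export
extract_features53 <- function(samples, framing = framing_config()) {
  mag <- stft_magnitude(samples, framing)
  shape <- spectral_shape(mag, framing$sample_rate, framing$window_samples)
  power <- pmax(mag^2, 1e-10)
  flatness <- exp(colMeans(log(power))) / colMeans(power)
  fw <- rbind(
    frame_mfcc(mag, framing$sample_rate, framing$window_samples),
    frame_zcr(samples, framing),
    flatness,
    shape$rolloff,
    shape$centroid,
    shape$bandwidth,
    frame_rmse(samples, framing)
  )
  out <- c(apply(fw, 1, mean), apply(fw, 1, pop_sd), peak_amplitude(samples))
  setNames(out, feature53_names())
}

#' Extract the 3-dimensional volume feature vector
#'
#' Mean and standard deviation of framewise RMSE plus peak amplitude:
#' the loudness-only description a volume baseline classifier sees.
#'
#' @inheritParams extract_features53
#' @return Named numeric vector `(mean_rmse, sd_rmse, peak_amplitude)`.
#' @export
extract_features3 <- function(samples, framing = framing_config()) {
  r <- frame_rmse(samples, framing)
  c(mean_rmse = mean(r), sd_rmse = pop_sd(r), peak_amplitude = peak_amplitude(samples))
}

#' Log-mel patches for the CNN front end
#'
#' Splits a segment into 2-s patches (a 5-s segment gives three: 2 s, 2 s
#' and a 1-s tail); patches shorter than 2 s are replicated until they
#' reach 2 s. Each patch becomes a 96-band log-mel spectrogram with a
#' 40-ms window and 50% overlap (882/441 samples at 22,050 Hz, FFT size
#' 1024, mel range 0-11,025 Hz, natural log with floor `1e-10`), giving a
#' 96 x 101 matrix under centered framing.
#'
#' @param samples Mono waveform at 22,050 Hz.
#' @param patch_seconds Patch length in seconds (default 2).
#' @return List of 96 x 101 log-mel matrices.
#' @export
logmel_patches <- function(samples, patch_seconds = 2) {
  plen <- as.integer(patch_seconds * CANONICAL_SR)
  n <- length(samples)
  n_patches <- max(1L, as.integer(ceiling(n / plen)))
  lapply(seq_len(n_patches), function(i) {
    chunk <- samples[(((i - 1L) * plen) + 1L):min(i * plen, n)]
    if (length(chunk) < plen) {
      chunk <- rep_len(rep(chunk, ceiling(plen / length(chunk))), plen)
    }
    logmel_matrix(chunk)
  })
}

## 96-band log-mel spectrogram of a 2-s chunk
logmel_matrix <- function(chunk, n_mels = 96L) {
  framing <- framing_config(window_samples = 882L, hop_samples = 441L,
                            centered = TRUE, sample_rate = CANONICAL_SR)
  mag <- stft_magnitude(chunk, framing, n_fft = 1024L)
  fb <- mel_filterbank(n_mels, 1024L, CANONICAL_SR)
  log(pmax(fb %*% (mag^2), 1e-10))
}

#' Per-participant mean frame RMSE
#'
#' Grand mean of all framewise RMSE values over every segment of each
#' participant's recording; the normaliser behind the detector's 3x
#' cry/babble and 7x loudness-override rules.
#'
#' @param segments Segment tibble with `participant_id` and `samples`.
#' @param framing A [framing_config()].
#' @return Tibble: `participant_id`, `mean_rmse`, `n_frames`.
#' @export
participant_mean_rmse <- function(segments, framing = framing_config()) {
  assert_columns(segments, c("participant_id", "samples"), "segment table")
  if (nrow(segments) == 0) abort("Cannot compute participant stats on an empty recording.")
  segments |>
    dplyr::mutate(.rmse = lapply(.data$samples, frame_rmse, framing = framing)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      mean_rmse = mean(unlist(.data$.rmse)),
      n_frames = length(unlist(.data$.rmse)),
      .groups = "drop"
    )
}

#' Per-segment acoustic summary used by the detector
#'
#' Computes, for every segment, the quantities the pruning heuristics and
#' the loudness override consult: the maximum frame RMSE, whether all
#' spectral flatness values exceed the white-noise threshold, the
#' zero-crossing count and the peak amplitude.
#'
#' @param segments Segment tibble with `participant_id`, `segment_index`,
#'   `samples`.
#' @param framing A [framing_config()].
#' @param flatness_threshold White-noise flatness signature (default `1e-4`).
#' @return Tibble keyed by participant/segment with columns `max_rmse`,
#'   `all_flatness_above`, `zero_crossings`, `peak_amplitude`.
#' @export
segment_audio_summary <- function(segments, framing = framing_config(),
                                  flatness_threshold = 1e-4) {
  assert_columns(segments, c("participant_id", "segment_index", "samples"),
                 "segment table")
  segments |>
    dplyr::mutate(
      max_rmse = vapply(.data$samples, function(x) max(frame_rmse(x, framing)), numeric(1)),
      all_flatness_above = vapply(.data$samples, function(x) {
        all(spectral_flatness_series(x, framing) > flatness_threshold)
      }, logical(1)),
      zero_crossings = vapply(.data$samples, zero_crossings, integer(1)),
      peak_amplitude = vapply(.data$samples, peak_amplitude, numeric(1))
    ) |>
    dplyr::select(-"samples")
}

#' Segment-level feature table
#'
#' Data-frame interface over [extract_features53()] / [extract_features3()]:
#' one row per segment, one column per feature, keys preserved.
#'
#' @param segments Segment tibble with `participant_id`, `segment_index`,
#'   `samples` (and optionally `chaos_level`, carried through).
#' @param set `"f53"` or `"f3"`.
#' @param framing A [framing_config()].
#' @return Tibble of keys (+ `chaos_level` if present) and feature columns.
#' @export
segment_features <- function(segments, set = c("f53", "f3"),
                             framing = framing_config()) {
  set <- match.arg(set)
  assert_columns(segments, c("participant_id", "segment_index", "samples"),
                 "segment table")
  fn <- if (set == "f53") extract_features53 else extract_features3
  feats <- do.call(rbind, lapply(segments$samples, fn, framing = framing))
  keep <- intersect(c("participant_id", "segment_index", "chaos_level"),
                    names(segments))
  dplyr::bind_cols(segments[keep], tibble::as_tibble(feats))
}

#' Log-mel patch table
#'
#' One row per 2-s patch with the source segment's keys and label.
#'
#' @inheritParams segment_features
#' @return Tibble: keys, `patch_index` (0-based) and `patch` list-column of
#'   96 x 101 log-mel matrices.
#' @export
segment_patches <- function(segments) {
  assert_columns(segments, c("participant_id", "segment_index", "samples"),
                 "segment table")
  keep <- intersect(c("participant_id", "segment_index", "chaos_level"),
                    names(segments))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    patches <- logmel_patches(segments$samples[[i]])
    out <- segments[rep(i, length(patches)), keep]
    out$patch_index <- seq_along(patches) - 1L
    out$patch <- patches
    out
  })
  tibble::as_tibble(dplyr::bind_rows(rows))
}
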