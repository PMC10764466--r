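#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings produced by common
#' recorders: PCM 8-bit unsigned, PCM 16/24/32-bit signed, and IEEE float 32.
#' Samples are returned as floats in `[-1, 1]`, one column per channel.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric matrix, frames x channels),
#'   `sample_rate` (Hz) and `bit_depth`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  read_tag <- function() rawToChar(readBin(con, "raw", 4))
  read_u32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")

  if (read_tag() != "RIFF") abort(sprintf("Not a RIFF/WAVE file: %s", path))
  read_u32()
  if (read_tag() != "WAVE") abort(sprintf("Not a RIFF/WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- readBin(con, "raw", 4)
    if (length(tag) < 4) break
    tag <- rawToChar(tag)
    size <- read_u32()
    if (tag == "fmt ") {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (tag == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("Corrupt WAV (missing fmt/data chunk): %s", path))
  }

  bytes <- fmt$bits / 8
  n_total <- floor(length(data_raw) / bytes)
  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n_total, size = 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n_total, size = 2, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 8L) {
    (readBin(data_raw, "integer", n_total, size = 1, signed = FALSE) - 128) / 128
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw[seq_len(n_total * 3)])
    v <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
      65536 * b[seq(3, length(b), 3)]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n_total, size = 4, endian = "little") / 2147483648
  } else {
    abort(sprintf("Unsupported WAV encoding (format %d, %d-bit): %s",
                  fmt$format, fmt$bits, path))
  }

  n_frames <- floor(length(x) / fmt$channels)
  samples <- matrix(x[seq_len(n_frames * fmt$channels)],
                    ncol = fmt$channels, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate, bit_depth = fmt$bits)
}

#' Write a mono or multichannel waveform as 16-bit PCM WAV
#'
#' @param samples Numeric vector (mono) or matrix (frames x channels) in
#'   `[-1, 1]`; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz (default the canonical 22,050).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 22050L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  channels <- ncol(samples)
  x <- t(samples) # interleave channels
  pcm <- as.integer(pmax(-32768, pmin(32767, round(as.numeric(x) * 32767))))

  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")

  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(channels); w32(sample_rate)
  w32(sample_rate * channels * 2L); w16(channels * 2L); w16(16L)
  writeChar("data", con, eos = NULL); w32(data_size)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
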