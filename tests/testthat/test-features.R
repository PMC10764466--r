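## Independent brute-force oracles: explicit per-frame loops with manual
## padding and a direct DFT, sharing no code with the implementation.

oracle_frames <- function(x, window = 512, hop = 256) {
  padded <- c(numeric(window %/% 2), x, numeric(window))
  nf <- 1 + floor(length(x) / hop)
  lapply(seq_len(nf), function(f) padded[((f - 1) * hop + 1):((f - 1) * hop + window)])
}

oracle_dft_mag <- function(frame) {
  n <- length(frame)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  v <- frame * w
  k <- 0:(n / 2)
  sapply(k, function(kk) Mod(sum(v * exp(-2i * pi * kk * (0:(n - 1)) / n))))
}

test_that("centered framing of a 5-s segment yields exactly 431 frames", {
  x <- rnorm(110250)
  expect_length(frame_rmse(x), 431L)
  expect_length(spectral_flatness_series(x), 431L)
  expect_identical(n_frames(110250), 431L)
})

test_that("frame counts obey 1 + floor(n/hop) for arbitrary lengths", {
  set.seed(10)
  for (n in sample(1000:50000, 8)) {
    x <- rnorm(n)
    expect_length(frame_rmse(x), 1L + floor(n / 256))
  }
})

test_that("frame RMSE matches a brute-force per-frame oracle", {
  set.seed(11)
  x <- runif(3000, -1, 1)
  expected <- vapply(oracle_frames(x), function(fr) sqrt(mean(fr^2)), numeric(1))
  expect_equal(frame_rmse(x), expected, tolerance = 1e-12)

  expect_true(all(frame_rmse(numeric(5000)) == 0))

  a <- rep(0.3, 4000)
  r <- frame_rmse(a)
  expect_equal(r[5:10], rep(0.3, 6), tolerance = 1e-12) # interior frames
  expect_lt(r[1], 0.3) # zero-padded edge frame
})

test_that("peak amplitude is the exhaustive maximum of |samples|", {
  expect_equal(peak_amplitude(make_sine(440, amp = 0.5)), 0.5, tolerance = 1e-6)
  expect_equal(peak_amplitude(numeric(100)), 0)
  set.seed(12)
  x <- rnorm(5000)
  expect_equal(peak_amplitude(x), max(abs(x)))
})

test_that("spectral flatness separates white noise from tones at the 1e-4 threshold", {
  set.seed(13)
  noise <- rnorm(110250) * 0.3
  fn <- spectral_flatness_series(noise)
  expect_true(all(fn > 1e-4))
  expect_true(all(fn <= 1))

  tone <- make_sine(440, amp = 0.5)
  ft <- spectral_flatness_series(tone)
  expect_false(all(ft > 1e-4))
  expect_true(all(ft[3:429] < 1e-4)) # interior frames are near zero
  expect_true(all(ft >= 0))
})

test_that("flatness, centroid, bandwidth and rolloff match a direct-DFT oracle", {
  set.seed(14)
  x <- runif(1500, -1, 1) + make_sine(700, 0.3, 1)[1:1500]
  frames <- oracle_frames(x)
  mags <- lapply(frames, oracle_dft_mag)
  freqs <- (0:256) * 22050 / 512

  o_flat <- vapply(mags, function(m) {
    p <- pmax(m^2, 1e-10)
    exp(mean(log(p))) / mean(p)
  }, numeric(1))
  o_cent <- vapply(mags, function(m) sum(freqs * m) / sum(m), numeric(1))
  o_bw <- vapply(seq_along(mags), function(i) {
    sqrt(sum(mags[[i]] * (freqs - o_cent[i])^2) / sum(mags[[i]]))
  }, numeric(1))
  o_roll <- vapply(mags, function(m) {
    freqs[which(cumsum(m) >= 0.85 * sum(m))[1]]
  }, numeric(1))

  expect_equal(spectral_flatness_series(x), o_flat, tolerance = 1e-8)
  f53 <- extract_features53(x)
  expect_equal(unname(f53["mean_centroid"]), mean(o_cent), tolerance = 1e-8)
  expect_equal(unname(f53["mean_bandwidth"]), mean(o_bw), tolerance = 1e-8)
  expect_equal(unname(f53["mean_rolloff"]), mean(o_roll), tolerance = 1e-8)
})

test_that("segment-level zero crossings count sign changes through zero", {
  expect_identical(zero_crossings(numeric(1000)), 0L)
  n <- 500
  alt <- rep(c(0.4, -0.4), length.out = n)
  expect_equal(zero_crossings(alt), n - 1)
  s <- make_sine(100) # 500 cycles over 5 s
  direct <- {
    sg <- sign(s); sg <- sg[sg != 0]; sum(diff(sg) != 0)
  }
  expect_equal(zero_crossings(s), direct)
  expect_true(abs(zero_crossings(s) - 1000) <= 1)
})

test_that("extract_features53 returns 53 named values in the documented order", {
  set.seed(15)
  f <- extract_features53(rnorm(110250) * 0.2)
  expect_length(f, 53L)
  expect_identical(names(f), chaoscope:::feature53_names())
  expect_identical(names(f)[1], "mean_mfcc_1")
  expect_identical(names(f)[27], "sd_mfcc_1")
  expect_identical(names(f)[53], "peak_amplitude")
})

test_that("framewise means/stds in the 53-vector agree with two-pass recomputation", {
  set.seed(16)
  x <- runif(110250, -0.5, 0.5)
  f <- extract_features53(x)
  r <- frame_rmse(x)
  expect_equal(unname(f["mean_rmse"]), mean(r), tolerance = 1e-12)
  expect_equal(unname(f["sd_rmse"]), sqrt(mean((r - mean(r))^2)), tolerance = 1e-12)
  fl <- spectral_flatness_series(x)
  expect_equal(unname(f["mean_flatness"]), mean(fl), tolerance = 1e-12)
  expect_equal(unname(f["peak_amplitude"]), max(abs(x)))

  ## constant segment: interior frames identical, so stds collapse to the
  ## small edge-padding contribution
  fc <- extract_features53(rep(0.4, 110250))
  expect_lt(unname(fc["sd_rmse"]), 0.05)
  expect_equal(unname(fc["peak_amplitude"]), 0.4)
})

test_that("extract_features53 and extract_features3 are pure and deterministic", {
  set.seed(17)
  x <- rnorm(110250) * 0.1
  expect_identical(extract_features53(x), extract_features53(x))
  f3 <- extract_features3(x)
  expect_identical(f3, extract_features3(x))
  expect_named(f3, c("mean_rmse", "sd_rmse", "peak_amplitude"))
  expect_equal(unname(f3["mean_rmse"]), mean(frame_rmse(x)), tolerance = 1e-12)
  expect_identical(unname(extract_features3(numeric(110250))), c(0, 0, 0))
})

test_that("a 5-s segment yields three 96-band 2-s log-mel patches", {
  set.seed(18)
  x <- rnorm(110250) * 0.2
  p <- logmel_patches(x)
  expect_length(p, 3L)
  for (m in p) expect_identical(dim(m), c(96L, 101L))
})

test_that("short trailing patches are replicated to 2 s before transform", {
  set.seed(19)
  x <- rnorm(3 * 22050) * 0.2 # 3 s: one full patch + 1-s tail
  p <- logmel_patches(x)
  expect_length(p, 2L)
  tail1s <- x[(2 * 22050 + 1):(3 * 22050)]
  expect_equal(p[[2]], chaoscope:::logmel_matrix(c(tail1s, tail1s)))

  exact <- rnorm(44100) * 0.1 # exactly 2 s: single patch, no replication
  pe <- logmel_patches(exact)
  expect_length(pe, 1L)
  expect_equal(pe[[1]], chaoscope:::logmel_matrix(exact))
})

test_that("participant mean RMSE is the grand mean over all frames of all segments", {
  segs <- dplyr::bind_rows(
    as_segment(make_sine(300, 0.2), index = 0L),
    as_segment(numeric(110250), index = 1L)
  )
  stats <- participant_mean_rmse(segs)
  manual <- mean(c(frame_rmse(segs$samples[[1]]), frame_rmse(segs$samples[[2]])))
  expect_equal(stats$mean_rmse, manual, tolerance = 1e-12)
  expect_equal(stats$n_frames, 862L)

  zero <- participant_mean_rmse(as_segment(numeric(110250)))
  expect_equal(zero$mean_rmse, 0)

  const <- participant_mean_rmse(as_segment(rep(0.3, 110250)))
  expect_equal(const$mean_rmse, 0.3, tolerance = 0.01) # edge-padding bias only

  expect_error(participant_mean_rmse(as_segment(numeric(110250))[0, ]), "empty")
})
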