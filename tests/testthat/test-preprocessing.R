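test_that("noise profile is the per-bin mean of |STFT|^p to the 1/p", {
  # a single-frame profile equals that frame's magnitude exactly
  sig <- with_seed_test(3, audio_signal(stats::rnorm(4096, sd = 0.1), 22050))
  pr <- frame_params(1024, 512, center = FALSE)
  prof1 <- estimate_noise_profile(sig, pr, n_noise_frames = 1, p = 2)
  sp <- stft_magnitude(sig, pr)
  expect_equal(prof1$magnitude_spectrum, sp$magnitude[, 1], tolerance = 1e-12)

  # leading silence gives a (near-)zero profile even if a tone follows
  padded <- audio_signal(c(numeric(8192), gen_tone(1000, 0.5)$samples), 22050)
  prof0 <- estimate_noise_profile(padded, frame_params(1024, 512, center = FALSE),
                                  n_noise_frames = 5)
  expect_lt(max(prof0$magnitude_spectrum), 1e-12)

  expect_error(estimate_noise_profile(gen_tone(500, 0.05), n_noise_frames = 100),
               "n_noise_frames")
})

test_that("white-noise profile is flat across bins within 3 dB", {
  noise <- with_seed_test(5, audio_signal(stats::rnorm(22050 * 10, sd = 0.1), 22050))
  prof <- estimate_noise_profile(noise, n_noise_frames = 400, p = 2)
  m <- prof$magnitude_spectrum
  expect_lt(20 * log10(max(m) / min(m)), 3)
})

test_that("subtracting a zero noise profile is the identity", {
  sig <- with_seed_test(7, audio_signal(stats::rnorm(10000, sd = 0.2), 22050))
  zero <- estimate_noise_profile(audio_signal(numeric(22050), 22050),
                                 n_noise_frames = 5)
  out <- spectral_subtract(sig, zero)
  expect_equal(length(out$samples), length(sig$samples))
  expect_lt(max(abs(out$samples - sig$samples)), 1e-6)
})

test_that("self-subtraction flattens stationary tonal noise below 20% RMS", {
  hum <- hum_fixture(seed = 8)
  prof <- estimate_noise_profile(hum, n_noise_frames = 40, p = 1)
  out <- spectral_subtract(hum, prof)
  expect_lt(rms(out) / rms(hum), 0.20)
})

test_that("white-noise self-subtraction leaves the rectified residual", {
  # p = 2 with beta = 0 half-wave rectification leaves e^-1 of the power
  # (~0.61 RMS); the implementation should reproduce that, not beat it.
  noise <- with_seed_test(5, audio_signal(stats::rnorm(44100, sd = 0.1), 22050))
  prof <- estimate_noise_profile(noise, n_noise_frames = 40, p = 2)
  out <- spectral_subtract(noise, prof)
  expect_equal(rms(out) / rms(noise), exp(-0.5), tolerance = 0.08)
})

test_that("denoising a noisy tone improves the tone-bin SNR", {
  tone <- gen_tone(2002.6, 2.0)  # bin-aligned at the default geometry
  noisy <- add_noise(tone, "white", 10, seed = 2)
  noise_clip <- with_seed_test(9, audio_signal(
    stats::rnorm(44100) * sqrt(mean(tone$samples^2) / 10), 22050))
  prof <- estimate_noise_profile(noise_clip, n_noise_frames = 40)
  den <- spectral_subtract(noisy, prof)

  snr_est <- function(s) {
    sp <- stft_magnitude(s)
    pk <- which.min(abs(sp$bin_freqs - 2002.6))
    10 * log10(mean(sp$magnitude[pk, ]^2) /
                 mean(sp$magnitude[-((pk - 2):(pk + 2)), ]^2))
  }
  expect_gt(snr_est(den), snr_est(noisy))
})

test_that("profile/params bin mismatch raises a dimension error", {
  sig <- gen_tone(1000, 0.5)
  prof <- estimate_noise_profile(sig, frame_params(512, 256))
  expect_error(spectral_subtract(sig, prof, frame_params(1024, 512)), "bins")
})

test_that("short-time energy and ZCR match brute-force loops", {
  expect_equal(short_time_energy(matrix(c(1, -1, 1, -1), 1)), 4)
  expect_equal(short_time_energy(matrix(0, 3, 8)), c(0, 0, 0))
  expect_equal(zero_crossing_rate(matrix(c(1, -1, 1, -1), 1)), 3)
  expect_equal(zero_crossing_rate(matrix(0.5, 2, 6)), c(0, 0))

  frames <- with_seed_test(13, matrix(stats::rnorm(200 * 32), 200, 32))
  e_oracle <- apply(frames, 1, function(f) {
    acc <- 0; for (v in f) acc <- acc + v^2; acc
  })
  z_oracle <- apply(frames, 1, function(f) {
    s <- ifelse(f >= 0, 1, -1)
    acc <- 0
    for (n in 2:length(f)) acc <- acc + abs(s[n] - s[n - 1])
    acc / 2
  })
  expect_equal(short_time_energy(frames), e_oracle, tolerance = 1e-12)
  expect_identical(zero_crossing_rate(frames), z_oracle)

  pm <- with_seed_test(14, matrix(sample(c(-1, 1), 50 * 16, TRUE), 50, 16))
  z2 <- apply(pm, 1, function(f) sum(diff(f) != 0))
  expect_identical(zero_crossing_rate(pm), as.numeric(z2))
})

test_that("the voicing threshold is mean + 0.5 sd", {
  s <- c(0.3, 0.5, 0.7)  # mean 0.5
  s <- 0.5 + (s - 0.5) * (0.2 / stats::sd(s))  # rescale to sd exactly 0.2
  expect_equal(mean(s) + 0.5 * stats::sd(s), 0.6)
  expect_equal(logmelaci:::vad_threshold(s), 0.6)
})

test_that("endpoint detection recovers a planted segment within one hop", {
  fx <- planted_segments_fixture(seed = 3, snr_db = 30, duration = 1.5,
                                 syllable_rate = 2 / 3)
  det <- detect_endpoints(fx$signal)
  expect_equal(nrow(det$segments), 1)
  expect_equal(boundary_recovery(det$segments, fx$ground_truth$segments, 512), 1)
})

test_that("endpoint detection is invariant to global gain", {
  fx <- planted_segments_fixture(seed = 4)
  d1 <- detect_endpoints(fx$signal)
  scaled <- fx$signal
  scaled$samples <- scaled$samples * 37.5
  d2 <- detect_endpoints(scaled)
  expect_identical(d1$frame_decisions, d2$frame_decisions)
  expect_identical(d1$segments, d2$segments)
})

test_that("all-silent input yields no segments, with a warning", {
  silent <- audio_signal(numeric(22050), 22050)
  expect_warning(det <- detect_endpoints(silent), "constant")
  expect_equal(nrow(det$segments), 0)
  expect_false(any(det$frame_decisions))
})

test_that("or-mode flags a frame voiced when either feature crosses", {
  fx <- planted_segments_fixture(seed = 6)
  do_ <- detect_endpoints(fx$signal, mode = "or")
  # or-mode is the union of the two single-feature rules, so it can only
  # add voiced frames relative to an energy-only pass
  de <- detect_endpoints(fx$signal, energy_weight = 1)
  expect_true(all(do_$frame_decisions[de$frame_decisions]))
  expect_s3_class(do_, "segment_list")
})

test_that("segments can be extracted as audio", {
  fx <- planted_segments_fixture(seed = 5, duration = 4)
  det <- detect_endpoints(fx$signal)
  expect_gt(nrow(det$segments), 0)
  seg <- extract_segment(fx$signal, det, 1)
  expect_s3_class(seg, "audio_signal")
  expect_equal(length(seg$samples),
               det$segments$end_sample[1] - det$segments$start_sample[1])
})
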