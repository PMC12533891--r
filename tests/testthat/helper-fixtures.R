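# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (explicit loops, direct DFT sums) so they stay
# independent of the vectorized implementation paths they check.

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

rms <- function(x) {
  if (inherits(x, "audio_signal")) x <- x$samples
  sqrt(mean(x^2))
}

# Direct DFT magnitude of one frame (O(N^2)); oracle for stft_magnitude.
dft_magnitude_oracle <- function(frame) {
  N <- length(frame)
  n_bins <- N %/% 2 + 1
  sapply(seq_len(n_bins) - 1, function(k) {
    re <- sum(frame * cos(-2 * pi * k * (seq_len(N) - 1) / N))
    im <- sum(frame * sin(-2 * pi * k * (seq_len(N) - 1) / N))
    sqrt(re^2 + im^2)
  })
}

# Double-loop Mel projection oracle.
mel_project_oracle <- function(weights, mag) {
  out <- matrix(0, nrow(weights), ncol(mag))
  for (k in seq_len(nrow(weights))) {
    for (t in seq_len(ncol(mag))) {
      out[k, t] <- sum(weights[k, ] * mag[, t])
    }
  }
  out
}

# Double-loop DCT-II cepstrum oracle.
mfcc_oracle <- function(mel, n_coeffs, eps = 1e-10) {
  M <- nrow(mel)
  out <- matrix(0, n_coeffs, ncol(mel))
  for (n in 0:(n_coeffs - 1)) {
    for (t in seq_len(ncol(mel))) {
      acc <- 0
      for (m in 0:(M - 1)) {
        acc <- acc + log(mel[m + 1, t] + eps) * cos(n * (m + 0.5) * pi / M)
      }
      out[n + 1, t] <- acc
    }
  }
  out
}

# Direct evaluation of the regression-delta formula with replicate padding.
delta_oracle <- function(coeffs, N) {
  T_ <- ncol(coeffs)
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, nrow(coeffs), T_)
  for (t in seq_len(T_)) {
    for (n in -N:N) {
      tt <- min(max(t + n, 1), T_)
      out[, t] <- out[, t] + n * coeffs[, tt]
    }
  }
  out / denom
}

# Brute-force per-frame Log-Mel ACI (double loop over bands and frames).
logmel_aci_oracle <- function(lm, eps = 1e-12) {
  T_ <- ncol(lm)
  vals <- numeric(T_ - 1)
  for (t in seq_len(T_ - 1)) {
    num <- 0
    den <- 0
    for (k in seq_len(nrow(lm))) {
      num <- num + abs(lm[k, t + 1] - lm[k, t])
      den <- den + lm[k, t]
    }
    vals[t] <- if (den < eps) 0 else num / den
  }
  vals
}

# Scale a signal to a target RMS (Log-Mel ACI is amplitude-sensitive, so
# rhythm comparisons fix the RMS).
scale_to_rms <- function(signal, target) {
  signal$samples <- signal$samples * (target / rms(signal$samples))
  signal
}

# Planted-segment VAD fixture: flat-top (Tukey) chirp syllables over pink
# background noise, with exact ground-truth boundaries.
planted_segments_fixture <- function(seed, snr_db = 20, duration = 6,
                                     syllable_rate = 0.5, syllable_dur = 0.5) {
  sp <- syllable_train_spec(
    syllable_rate = syllable_rate, f_start = 2000, f_end = 4000,
    syllable_dur = syllable_dur, duration = duration, seed = seed,
    jitter_frac = 0.5, envelope = "tukey"
  )
  g <- gen_chirp_train(sp)
  list(signal = add_noise(g$signal, "pink", snr_db, seed = seed + 1000L),
       ground_truth = g$ground_truth)
}

# Fraction of ground-truth boundaries matched by a detected boundary
# within `tol` samples.
boundary_recovery <- function(detected, truth, tol) {
  truth_b <- c(truth$start_sample, truth$end_sample)
  det_b <- c(detected$start_sample, detected$end_sample)
  if (length(det_b) == 0) return(0)
  mean(sapply(truth_b, function(b) any(abs(det_b - b) <= tol)))
}

# Stationary machinery-hum fixture (harmonic stack + weak broadband floor):
# the canonical stationary-noise regime for spectral subtraction.
hum_fixture <- function(seed = 8, dur_s = 2, sr = 22050) {
  t <- (seq_len(dur_s * sr) - 1) / sr
  hum <- audio_signal(
    0.2 * sin(2 * pi * 120 * t) + 0.1 * sin(2 * pi * 240 * t) +
      0.05 * sin(2 * pi * 363 * t), sr
  )
  add_noise(hum, "white", 15, seed = seed)
}
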