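# Denoising and endpoint detection.
#
# Denoising is classical spectral subtraction: estimate a stationary noise
# magnitude spectrum, subtract it (in amplitude, p = 1, or power, p = 2)
# from every frame, and resynthesize with the original phase. Endpoint
# detection combines min-max-normalized short-time energy and zero-crossing
# rate against a data-driven threshold mean + 0.5 * sd.

#' Estimate a stationary noise magnitude spectrum
#'
#' Averages `|STFT|^p` over the first `n_noise_frames` frames (assumed to
#' contain background noise only) and takes the 1/p power. The estimation
#' window is an explicit argument so a separate noise-only clip can supply
#' the profile instead of the recording's own lead-in.
#'
#' @param signal An [audio_signal()].
#' @param params A [frame_params()] object.
#' @param n_noise_frames Number of leading frames to average (default 5).
#' @param p Power exponent: 1 for amplitude-spectrum, 2 for power-spectrum
#'   subtraction.
#' @return An object of class `noise_profile` with fields
#'   `magnitude_spectrum` (one value per frequency bin), `n_frames_used`,
#'   `power_exponent_p` and `frame_length`.
#' @seealso [spectral_subtract()]
#' @export
estimate_noise_profile <- function(signal, params = frame_params(),
                                   n_noise_frames = 5L, p = 2) {
  if (!p %in% c(1, 2)) stopf("`p` must be 1 or 2")
  if (!is_count(n_noise_frames)) stopf("`n_noise_frames` must be a positive integer")
  sp <- stft_magnitude(signal, params)
  T_ <- ncol(sp$magnitude)
  if (T_ < n_noise_frames) {
    stopf("signal yields only %d frames; use n_noise_frames <= %d", T_, T_)
  }
  m <- sp$magnitude[, seq_len(n_noise_frames), drop = FALSE]
  prof <- rowMeans(m^p)^(1 / p)
  structure(
    list(
      magnitude_spectrum = prof,
      n_frames_used = as.integer(n_noise_frames),
      power_exponent_p = p,
      frame_length = params$frame_length
    ),
    class = "noise_profile"
  )
}

#' Spectral-subtraction denoising
#'
#' Per frame, the subtracted magnitude satisfies
#' `|X|^p = max(|Y|^p - |D|^p, floor_beta * |D|^p)` where `|Y|` is the
#' frame magnitude and `|D|` the noise profile; the noisy phase is reused
#' and the signal is resynthesized by overlap-add to the input length.
#' `floor_beta = 0` is half-wave rectification; a small positive value
#' leaves a noise floor that suppresses musical noise.
#'
#' @param signal An [audio_signal()].
#' @param noise A `noise_profile` from [estimate_noise_profile()], with a
#'   matching bin count.
#' @param params A [frame_params()] object (must match the profile's
#'   frame length).
#' @param floor_beta Non-negative spectral floor coefficient (default 0).
#' @return A denoised [audio_signal()] of the same length and rate.
#' @export
spectral_subtract <- function(signal, noise, params = frame_params(),
                              floor_beta = 0) {
  stopifnot(inherits(noise, "noise_profile"))
  if (floor_beta < 0) stopf("`floor_beta` must be >= 0")
  n_bins <- params$frame_length %/% 2 + 1L
  if (length(noise$magnitude_spectrum) != n_bins) {
    stopf("noise profile has %d bins but params imply %d",
          length(noise$magnitude_spectrum), n_bins)
  }
  p <- noise$power_exponent_p
  X <- stft_complex(signal, params)
  mag <- Mod(X)
  dp <- noise$magnitude_spectrum^p
  sub <- pmax(mag^p - dp, floor_beta * dp)  # dp recycles down columns
  new_mag <- sub^(1 / p)
  scale <- ifelse(mag > 0, new_mag / mag, 0)
  y <- istft(X * scale, params, length(signal$samples))
  audio_signal(y, signal$sample_rate, source_id = signal$source_id)
}

#' Short-time energy per frame
#'
#' Sum of squared samples within each analysis frame.
#'
#' @param frames A frame matrix from [frame_signal()] (one row per frame).
#' @return Non-negative numeric vector, one energy per frame.
#' @export
short_time_energy <- function(frames) {
  stopifnot(is.matrix(frames))
  rowSums(frames^2)
}

#' Zero-crossing count per frame
#'
#' Half the sum of `|sgn(x[n]) - sgn(x[n-1])|` over each frame, i.e. the
#' number of sign changes. `sgn(0)` is taken as +1 so silent frames score 0.
#'
#' @param frames A frame matrix with at least 2 columns.
#' @return Integer-valued vector in `[0, N - 1]`, one count per frame.
#' @export
zero_crossing_rate <- function(frames) {
  stopifnot(is.matrix(frames))
  if (ncol(frames) < 2) stopf("frames must have length >= 2")
  s <- ifelse(frames >= 0, 1, -1)
  n <- ncol(s)
  rowSums(abs(s[, -1, drop = FALSE] - s[, -n, drop = FALSE])) / 2
}

# Min-max normalization to [0, 1]; constant vectors map to all zeros.
minmax_norm <- function(v) {
  r <- range(v)
  if (r[2] - r[1] <= 0) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

# Data-driven voicing threshold.
vad_threshold <- function(s) mean(s) + 0.5 * stats::sd(s)

#' Detect voiced segments by energy and zero-crossing rate
#'
#' Per frame, short-time energy and zero-crossing rate are min-max
#' normalized over the whole recording and combined as
#' `s = w * E + (1 - w) * Z`; a frame is voiced when `s` exceeds
#' `mean(s) + 0.5 * sd(s)`. Maximal voiced runs shorter than
#' `min_segment_frames` are discarded, and the surviving runs are mapped
#' back to sample coordinates using the full window support of their first
#' and last frames. Because both features are min-max normalized, the
#' decision is invariant to global amplitude scaling.
#'
#' With `mode = "or"` the literal either/or rule is used instead: each
#' feature is thresholded separately (mean + 0.5 sd of that feature) and a
#' frame is voiced when either exceeds its threshold.
#'
#' @param signal An [audio_signal()] yielding at least 2 frames.
#' @param params A [frame_params()] object.
#' @param energy_weight Weight `w` of the energy term in the combined
#'   feature, in \[0, 1\] (default 0.5). Ignored for `mode = "or"`.
#' @param min_segment_frames Minimum voiced-run length in frames
#'   (default 3).
#' @param mode `"weighted"` (default) or `"or"`.
#' @return An object of class `segment_list`: a list with `segments`
#'   (a tibble with 0-based half-open `start_sample`, `end_sample` and
#'   their second equivalents `start_s`, `end_s`), `frame_decisions`
#'   (logical per frame) and `threshold_used`.
#' @export
detect_endpoints <- function(signal, params = frame_params(),
                             energy_weight = 0.5, min_segment_frames = 3L,
                             mode = c("weighted", "or")) {
  mode <- match.arg(mode)
  if (energy_weight < 0 || energy_weight > 1) stopf("`energy_weight` must be in [0, 1]")
  frames <- frame_signal(signal, params)
  if (nrow(frames) < 2) stopf("signal yields fewer than 2 frames")
  e <- minmax_norm(short_time_energy(frames))
  z <- minmax_norm(zero_crossing_rate(frames))

  if (mode == "weighted") {
    s <- energy_weight * e + (1 - energy_weight) * z
    if (stats::sd(s) == 0) {
      warnf("combined energy/ZCR feature is constant; classifying all frames silent")
      voiced <- rep(FALSE, length(s))
      thr <- NA_real_
    } else {
      thr <- vad_threshold(s)
      voiced <- s > thr
    }
  } else {
    if (stats::sd(e) == 0 && stats::sd(z) == 0) {
      warnf("energy and ZCR are both constant; classifying all frames silent")
      voiced <- rep(FALSE, length(e))
      thr <- NA_real_
    } else {
      thr_e <- vad_threshold(e)
      thr_z <- vad_threshold(z)
      voiced <- (e > thr_e) | (z > thr_z)
      thr <- thr_e
    }
  }

  runs <- rle(voiced)
  keep <- runs$values & runs$lengths >= min_segment_frames
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  L <- length(signal$samples)
  seg <- lapply(which(keep), function(i) {
    f0 <- starts[i] - 1L  # 0-based frame indices
    f1 <- ends[i] - 1L
    lo <- max(0L, frame_support(f0, params)[1])
    hi <- min(L, frame_support(f1, params)[2])
    c(lo, hi)
  })
  seg_tbl <- if (length(seg) == 0) {
    tibble::tibble(start_sample = integer(), end_sample = integer(),
                   start_s = numeric(), end_s = numeric())
  } else {
    m <- do.call(rbind, seg)
    tibble::tibble(
      start_sample = as.integer(m[, 1]), end_sample = as.integer(m[, 2]),
      start_s = m[, 1] / signal$sample_rate, end_s = m[, 2] / signal$sample_rate
    )
  }
  structure(
    list(segments = seg_tbl, frame_decisions = voiced, threshold_used = thr),
    class = "segment_list"
  )
}

#' @export
print.segment_list <- function(x, ...) {
  cat(sprintf("<segment_list> %d segment(s), %d/%d voiced frames, threshold %.4f\n",
              nrow(x$segments), sum(x$frame_decisions), length(x$frame_decisions),
              x$threshold_used))
  if (nrow(x$segments) > 0) print(x$segments)
  invisible(x)
}

#' Extract the audio of one detected segment
#'
#' @param signal The [audio_signal()] the segments were detected in.
#' @param segments A `segment_list` from [detect_endpoints()].
#' @param i Segment index (row of `segments$segments`).
#' @return An [audio_signal()] holding the segment's samples.
#' @export
extract_segment <- function(signal, segments, i) {
  stopifnot(inherits(segments, "segment_list"))
  seg <- segments$segments[i, ]
  audio_signal(signal$samples[(seg$start_sample + 1):seg$end_sample],
               signal$sample_rate,
               source_id = sprintf("%s[seg %d]", signal$source_id, i))
}
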