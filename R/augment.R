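# Data augmentation: pitch-preserving time stretch (phase vocoder), time
# shift with zero fill, and a driver that augments a class until a minimum
# total duration is reached.

#' Pitch-preserving time stretch
#'
#' Phase-vocoder stretch: the short-time magnitude envelope is resampled
#' along the time axis while per-bin phase is re-accumulated from the
#' measured instantaneous frequency, so spectral peaks stay at their
#' original frequencies. `speed < 1` slows the audio down
#' (`speed = 0.8` makes a 2 s signal about 2.5 s); `speed > 1` speeds it
#' up. Output duration is `duration / speed` within one hop.
#'
#' The recommended augmentation range is `speed` in \[0.8, 1.2\].
#'
#' @param signal An [audio_signal()].
#' @param speed Positive speed factor.
#' @param params Analysis [frame_params()] for the vocoder; the default
#'   uses a 1024-sample frame with a 256-sample hop (75% overlap) for
#'   smooth resynthesis.
#' @param method `"phase_vocoder"` (default, pitch-preserving) or
#'   `"resample"` (plain rate change: shifts pitch, provided for
#'   comparison only and not suitable as a pitch-preserving augmentation).
#' @return A stretched [audio_signal()] at the same sample rate.
#' @export
time_stretch <- function(signal, speed,
                         params = frame_params(1024L, 256L, "hann", TRUE),
                         method = c("phase_vocoder", "resample")) {
  method <- match.arg(method)
  if (!is.numeric(speed) || length(speed) != 1 || !is.finite(speed) || speed <= 0) {
    stopf("`speed` must be a positive finite scalar")
  }
  L <- length(signal$samples)
  len_out <- max(1L, as.integer(round(L / speed)))
  if (method == "resample") {
    # Changes duration by 1/speed but transposes pitch by `speed`.
    frac <- seq(0, L - 1, length.out = len_out)
    i0 <- pmin(floor(frac) + 1L, L)
    i1 <- pmin(i0 + 1L, L)
    a <- frac - floor(frac)
    y <- (1 - a) * signal$samples[i0] + a * signal$samples[i1]
    return(audio_signal(y, signal$sample_rate, source_id = signal$source_id))
  }

  X <- stft_complex(signal, params)
  n_bins <- nrow(X)
  T_ <- ncol(X)
  h <- params$hop_length
  # Output frame positions expressed as (0-based, fractional) input frames.
  steps <- seq(0, T_ - 1, by = speed)
  # Pad one zero frame so interpolation at the last step is defined.
  X <- cbind(X, complex(real = rep(0, n_bins)))
  omega <- 2 * pi * h * (seq_len(n_bins) - 1L) / params$frame_length
  phase <- Arg(X[, 1])
  out <- matrix(complex(real = 0), n_bins, length(steps))
  for (s in seq_along(steps)) {
    p0 <- floor(steps[s])
    frac <- steps[s] - p0
    c1 <- X[, p0 + 1L]
    c2 <- X[, p0 + 2L]
    mag <- (1 - frac) * Mod(c1) + frac * Mod(c2)
    out[, s] <- mag * exp(1i * phase)
    dphi <- Arg(c2) - Arg(c1) - omega
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + omega + dphi
  }
  y <- istft(out, params, len_out)
  audio_signal(y, signal$sample_rate, source_id = signal$source_id)
}

#' Time shift with zero fill
#'
#' Displaces the signal by `tau_ms` milliseconds (positive: delayed start)
#' at constant length; vacated samples are zero-filled. The recommended
#' augmentation range is 0-100 ms.
#'
#' @param signal An [audio_signal()].
#' @param tau_ms Shift in milliseconds, `|tau_ms|` at most the signal
#'   duration.
#' @return A shifted [audio_signal()] of identical length.
#' @export
time_shift <- function(signal, tau_ms) {
  L <- length(signal$samples)
  if (abs(tau_ms) / 1000 > duration(signal)) {
    stopf("|tau_ms| = %.1f exceeds the signal duration (%.1f ms)",
          abs(tau_ms), 1000 * duration(signal))
  }
  k <- as.integer(round(tau_ms * signal$sample_rate / 1000))
  y <- if (k == 0) {
    signal$samples
  } else if (k > 0) {
    c(numeric(k), signal$samples[seq_len(L - k)])
  } else {
    c(signal$samples[(-k + 1):L], numeric(-k))
  }
  audio_signal(y, signal$sample_rate, source_id = signal$source_id)
}

#' Augment a class of recordings to a minimum total duration
#'
#' Repeatedly applies a random pitch-preserving stretch (uniform in
#' `stretch_range`) followed by a random shift (uniform in
#' `shift_range_ms`) to copies of the inputs, cycling through them, until
#' the total duration of originals plus derived copies reaches
#' `min_total_seconds`. The originals are always retained; each derived
#' signal carries its parameters in an `augmentation` field, and the full
#' log is attached as the `"augmentation_log"` attribute (a tibble with
#' `source`, `speed`, `shift_ms`).
#'
#' @param signals Non-empty list of [audio_signal()] objects.
#' @param min_total_seconds Target minimum total duration in seconds
#'   (e.g. 1200 for a 20-minute class floor).
#' @param seed Integer seed making the augmentation sequence reproducible.
#' @param stretch_range Length-2 numeric, default `c(0.8, 1.2)`.
#' @param shift_range_ms Length-2 numeric, default `c(0, 100)`.
#' @return A list of [audio_signal()]s (originals first).
#' @export
augment_to_minimum <- function(signals, min_total_seconds, seed,
                               stretch_range = c(0.8, 1.2),
                               shift_range_ms = c(0, 100)) {
  if (length(signals) == 0) stopf("need at least one input signal")
  stopifnot(all(vapply(signals, inherits, TRUE, "audio_signal")))
  total <- sum(vapply(signals, duration, 0))
  out <- signals
  log <- list()
  if (total >= min_total_seconds) {
    attr(out, "augmentation_log") <-
      tibble::tibble(source = integer(), speed = numeric(), shift_ms = numeric())
    return(out)
  }
  with_seed(seed, {
    i <- 0L
    while (total < min_total_seconds) {
      src <- (i %% length(signals)) + 1L
      speed <- stats::runif(1, stretch_range[1], stretch_range[2])
      shift_ms <- stats::runif(1, shift_range_ms[1], shift_range_ms[2])
      y <- time_shift(time_stretch(signals[[src]], speed), shift_ms)
      y$augmentation <- list(source = src, speed = speed, shift_ms = shift_ms)
      out[[length(out) + 1L]] <- y
      log[[length(log) + 1L]] <- c(src, speed, shift_ms)
      total <- total + duration(y)
      i <- i + 1L
    }
  })
  m <- do.call(rbind, log)
  attr(out, "augmentation_log") <-
    tibble::tibble(source = as.integer(m[, 1]), speed = m[, 2], shift_ms = m[, 3])
  out
}
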